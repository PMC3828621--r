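#' Validate a run configuration
#'
#' Reads (or takes as a list) a declarative YAML configuration describing a
#' multi-protein run: per-protein input paths plus analysis options.  Unknown
#' keys raise an error (so typos never silently change an analysis), every
#' referenced path must exist, exposure thresholds must be ordered, and
#' defaults are filled in.
#'
#' Expected layout:
#' ```yaml
#' output_dir: out/
#' options:
#'   correlation_method: pearson   # or spearman
#'   entropy_pseudocount: false
#'   exposure: {scheme: three_class, buried_max: 0.05, partial_max: 0.25}
#'   control: {seed: 1, reps: 1}
#' hybrids:
#'   - {core: T0.1, surface: T0.6}
#' proteins:
#'   - id: p1
#'     natural: natural.fasta
#'     reference_id: first
#'     rsa_table: rsa.tsv          # or: dssp: file.dssp + chain: A
#'     designs: {T0.1: d1.fasta, T0.6: d2.fasta}
#' ```
#'
#' @param config Path to a YAML file, or an equivalent nested list.
#' @return Object of class `run_config` (the validated, default-filled list).
#' @seealso [run_comparison()]
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")

  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0L)
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(unknown, collapse = ", ")))
  }
  check_keys(config, c("output_dir", "options", "proteins", "hybrids"),
             "top level")
  if (is.null(config$proteins) || length(config$proteins) == 0L)
    stop("config must list at least one protein")

  opts <- config$options
  if (is.null(opts)) opts <- list()
  check_keys(opts, c("correlation_method", "entropy_pseudocount",
                     "exposure", "control"), "options")
  if (is.null(opts$correlation_method)) opts$correlation_method <- "pearson"
  if (!opts$correlation_method %in% c("pearson", "spearman"))
    stop("options.correlation_method must be 'pearson' or 'spearman'")
  if (is.null(opts$entropy_pseudocount)) opts$entropy_pseudocount <- FALSE
  exp_opts <- if (is.null(opts$exposure)) list() else opts$exposure
  check_keys(exp_opts, c("scheme", "buried_max", "partial_max"),
             "options.exposure")
  if (is.null(exp_opts$scheme)) exp_opts$scheme <- "three_class"
  if (is.null(exp_opts$buried_max)) exp_opts$buried_max <- 0.05
  if (is.null(exp_opts$partial_max)) exp_opts$partial_max <- 0.25
  # exposure_scheme() itself enforces the threshold ordering
  opts$exposure_scheme <- exposure_scheme(exp_opts$scheme,
                                          exp_opts$buried_max,
                                          exp_opts$partial_max)
  ctrl <- if (is.null(opts$control)) list() else opts$control
  check_keys(ctrl, c("seed", "reps"), "options.control")
  if (is.null(ctrl$seed)) ctrl$seed <- 1L
  if (is.null(ctrl$reps)) ctrl$reps <- 1L
  opts$control <- list(seed = as.integer(ctrl$seed),
                       reps = as.integer(ctrl$reps))
  config$options <- opts

  seen_ids <- character(0)
  for (i in seq_along(config$proteins)) {
    pr <- config$proteins[[i]]
    check_keys(pr, c("id", "natural", "reference_id", "rsa_table",
                     "dssp", "chain", "max_asa_scale", "designs"),
               sprintf("proteins[%d]", i))
    if (is.null(pr$id)) stop(sprintf("proteins[%d] has no id", i))
    if (pr$id %in% seen_ids) stop("duplicate protein id: ", pr$id)
    seen_ids <- c(seen_ids, pr$id)
    if (is.null(pr$natural)) stop(sprintf("protein '%s' has no natural alignment", pr$id))
    if (!file.exists(pr$natural))
      stop(sprintf("protein '%s': natural alignment not found: %s", pr$id, pr$natural))
    if (is.null(pr$reference_id)) pr$reference_id <- "first"
    has_tab <- !is.null(pr$rsa_table); has_dssp <- !is.null(pr$dssp)
    if (has_tab == has_dssp)
      stop(sprintf("protein '%s': provide exactly one of rsa_table or dssp", pr$id))
    if (has_tab && !file.exists(pr$rsa_table))
      stop(sprintf("protein '%s': rsa_table not found: %s", pr$id, pr$rsa_table))
    if (has_dssp) {
      if (!file.exists(pr$dssp))
        stop(sprintf("protein '%s': dssp file not found: %s", pr$id, pr$dssp))
      if (is.null(pr$chain))
        stop(sprintf("protein '%s': dssp input needs a chain", pr$id))
    }
    if (is.null(pr$max_asa_scale)) pr$max_asa_scale <- "theoretical"
    if (is.null(pr$designs) || length(pr$designs) == 0L)
      stop(sprintf("protein '%s' lists no design alignments", pr$id))
    if (is.null(names(pr$designs)) || any(!nzchar(names(pr$designs))))
      stop(sprintf("protein '%s': designs must be a condition->path mapping", pr$id))
    if (anyDuplicated(names(pr$designs)))
      stop(sprintf("protein '%s': duplicate condition tags", pr$id))
    for (cond in names(pr$designs))
      if (!file.exists(pr$designs[[cond]]))
        stop(sprintf("protein '%s': design '%s' not found: %s",
                     pr$id, cond, pr$designs[[cond]]))
    config$proteins[[i]] <- pr
  }
  if (!is.null(config$hybrids)) {
    for (i in seq_along(config$hybrids)) {
      hy <- config$hybrids[[i]]
      check_keys(hy, c("core", "surface"), sprintf("hybrids[%d]", i))
      if (is.null(hy$core) || is.null(hy$surface))
        stop(sprintf("hybrids[%d] needs both core and surface conditions", i))
    }
  }
  structure(config, class = "run_config")
}

# Load one protein's inputs according to its config entry.
load_protein_inputs <- function(pr) {
  natural <- read_alignment(pr$natural, reference_id = pr$reference_id,
                            source_label = "natural", condition = "natural")
  designs <- lapply(names(pr$designs), function(cond)
    read_alignment(pr$designs[[cond]], reference_id = "first",
                   source_label = "designed", condition = cond))
  names(designs) <- names(pr$designs)
  rsa <- if (!is.null(pr$rsa_table)) {
    read_rsa_table(pr$rsa_table)
  } else {
    compute_rsa(parse_dssp(pr$dssp, pr$chain),
                max_asa_table(pr$max_asa_scale))
  }
  list(natural = natural, designs = designs, rsa = rsa)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparison pipeline from a configuration
#'
#' Executes, for every protein in the configuration: input loading, per-site
#' statistics, KL divergences against the natural reference, RSA joining,
#' correlations and the split-half control; then dataset-level summaries,
#' pooled exposure-class amino-acid frequencies, and any requested hybrid
#' constructions.  A failure in one protein is recorded in the failure table
#' and does not abort the run.  If `output_dir` is set, all result tables are
#' written as TSV files (byte-stable given identical inputs and seeds) plus a
#' `run.log`.
#'
#' @param config A path to a YAML config, a list, or a validated
#'   `run_config`.
#' @return Object of class `run_result`: list with `report`
#'   (a [comparison_report()] over the successful proteins), `class_entropy`,
#'   `class_frequencies`, `hybrid_correlations`, `failures` (data frame) and
#'   `output_dir`.
#' @export
run_comparison <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  opts <- config$options
  failures <- data.frame(protein_id = character(0), error = character(0))
  comparisons <- list()
  inputs <- list()
  log_lines <- c(sprintf("designvar %s",
                         as.character(utils::packageVersion("designvar"))),
                 sprintf("control seed %d, reps %d",
                         opts$control$seed, opts$control$reps),
                 sprintf("correlation method: %s", opts$correlation_method))

  for (pr in config$proteins) {
    res <- tryCatch({
      inp <- load_protein_inputs(pr)
      map <- build_site_map(inp$natural)
      cmp <- compare_designs(inp$natural, inp$designs, inp$rsa, map = map,
                             method = opts$correlation_method,
                             scheme = opts$exposure_scheme,
                             control_seed = opts$control$seed,
                             control_reps = opts$control$reps,
                             entropy_pseudocount = opts$entropy_pseudocount,
                             protein_id = pr$id)
      list(cmp = cmp, inp = c(inp, list(map = map)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(protein_id = pr$id,
                                   error = conditionMessage(res)))
      log_lines <- c(log_lines,
                     sprintf("FAILED %s: %s", pr$id, conditionMessage(res)))
    } else {
      comparisons[[pr$id]] <- res$cmp
      inputs[[pr$id]] <- res$inp
      log_lines <- c(log_lines, sprintf("ok %s (%d sites)", pr$id,
                                        nrow(res$cmp$per_site)))
    }
  }
  if (length(comparisons) == 0L)
    stop("all proteins failed; first error: ", failures$error[1L])

  report <- comparison_report(comparisons)
  cls_ent <- class_entropy_summary(report$per_site_tables)

  two_class <- exposure_scheme("two_class",
                               buried_max = opts$exposure_scheme$buried_max)
  maps <- lapply(inputs, `[[`, "map")
  rsas <- lapply(inputs, `[[`, "rsa")
  sources <- c(list(natural = lapply(inputs, `[[`, "natural")),
               stats::setNames(
                 lapply(names(inputs[[1L]]$designs), function(cond)
                   lapply(inputs, function(x) x$designs[[cond]])),
                 names(inputs[[1L]]$designs)))
  class_freqs <- lapply(sources, function(alns)
    class_aa_frequencies(alns, maps, rsas, two_class))

  hybrid_cors <- NULL
  if (!is.null(config$hybrids)) {
    rows <- list()
    for (hy in config$hybrids) {
      recipe <- hybrid_recipe(hy$core, hy$surface, opts$exposure_scheme)
      for (pid in names(inputs)) {
        inp <- inputs[[pid]]
        if (!all(c(hy$core, hy$surface) %in% names(inp$designs))) {
          failures <- rbind(failures, data.frame(
            protein_id = pid,
            error = sprintf("hybrid %s+%s: condition missing", hy$core, hy$surface)))
          next
        }
        hyb <- build_hybrid(inp$designs[[hy$core]], inp$designs[[hy$surface]],
                            inp$map, inp$rsa, recipe)
        rows[[length(rows) + 1L]] <- hybrid_correlation_analysis(
          hyb, inp$natural, inp$map, inp$rsa,
          method = opts$correlation_method, protein_id = pid)
      }
    }
    if (length(rows) > 0L) hybrid_cors <- do.call(rbind, rows)
  }

  out <- structure(list(report = report, class_entropy = cls_ent,
                        class_frequencies = class_freqs,
                        hybrid_correlations = hybrid_cors,
                        failures = failures,
                        output_dir = config$output_dir),
                   class = "run_result")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_tsv(report$per_protein, file.path(od, "per_protein.tsv"))
    write_tsv(report$condition_summary, file.path(od, "condition_summary.tsv"))
    cors <- report$per_protein[, c("protein_id", "condition", "cor_r", "cor_n")]
    cors$method <- opts$correlation_method
    write_tsv(cors, file.path(od, "correlations.tsv"))
    write_tsv(cls_ent$summary, file.path(od, "class_entropy.tsv"))
    freq_tab <- do.call(rbind, lapply(names(class_freqs), function(src) {
      m <- class_freqs[[src]]
      data.frame(source = src, exposure_class = rownames(m),
                 as.data.frame(m, check.names = FALSE))
    }))
    write_tsv(freq_tab, file.path(od, "class_frequencies.tsv"))
    for (pid in names(report$per_site_tables))
      write_tsv(report$per_site_tables[[pid]],
                file.path(od, sprintf("per_site_%s.tsv", pid)))
    if (!is.null(hybrid_cors))
      write_tsv(hybrid_cors, file.path(od, "hybrid_correlations.tsv"))
    write_tsv(failures, file.path(od, "failures.tsv"))
    writeLines(log_lines, file.path(od, "run.log"))
  }
  out
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d protein(s) ok, %d failure(s)\n",
              length(x$report$per_site_tables), nrow(x$failures)))
  if (!is.null(x$output_dir)) cat("  outputs in:", x$output_dir, "\n")
  invisible(x)
}
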