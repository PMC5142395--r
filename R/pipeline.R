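# End-to-end pipeline: run configuration, the two-strategy comparison and
# its report object.

#' Run configuration
#'
#' Bundles every tunable of a screening run: thresholds, index
#' conventions, the simulation block and report options.  All defaults are
#' materialised on construction, so a dumped configuration is complete,
#' and unknown keys are rejected.
#'
#' @param thresholds a [screening_thresholds()] object.
#' @param conventions an [index_conventions()] object.
#' @param simulation a [sim_config()] object.
#' @param report list of report options: `rounding` (`"half_up"` or
#'   `"truncate"`), `denominator_override` (optional accuracy denominator),
#'   `ci_level`.
#' @return list of class `run_config`.
#' @export
run_config <- function(thresholds = screening_thresholds(),
                       conventions = index_conventions(),
                       simulation = sim_config(),
                       report = list()) {
  rep_defaults <- list(rounding = "half_up", denominator_override = NULL,
                       ci_level = 0.95)
  unknown <- setdiff(names(report), names(rep_defaults))
  if (length(unknown) > 0)
    stop("unknown report option(s): ", paste(unknown, collapse = ", "))
  rep_defaults[names(report)] <- report
  structure(list(thresholds = thresholds, conventions = conventions,
                 simulation = simulation, report = rep_defaults),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' `load_run_config(dump_run_config(cfg, path))` is the identity.
#'
#' @param config a [run_config()] object.
#' @param path output path.
#' @export
dump_run_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  # named atomic vectors must serialize as maps, not bare sequences
  to_plain <- function(x) {
    if (is.list(x)) lapply(unclass(x), to_plain)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_plain(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname dump_run_config
#' @return [load_run_config()] returns the reconstructed `run_config`.
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  raw <- yaml::read_yaml(path)
  known <- c("thresholds", "conventions", "simulation", "report")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  build <- function(fn, block) {
    if (is.null(block)) return(fn())
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (nm in names(block))
      if (is.list(block[[nm]]) && !is.null(names(block[[nm]])) &&
          !nm %in% c("ankle_ratio", "toe_ratio"))
        block[[nm]] <- unlist(block[[nm]])
    for (nm in c("level_split", "mac_logit", "mac_inflation",
                 "age_range", "brachial_range"))
      if (!is.null(block[[nm]])) block[[nm]] <- unlist(block[[nm]])
    for (nm in c("ankle_ratio", "toe_ratio"))
      if (!is.null(block[[nm]]))
        block[[nm]] <- lapply(block[[nm]], unlist)
    do.call(fn, block)
  }
  run_config(thresholds = build(screening_thresholds, raw$thresholds),
             conventions = build(index_conventions, raw$conventions),
             simulation = build(sim_config, raw$simulation),
             report = raw$report %||% list())
}

#' Compare both screening strategies on one cohort
#'
#' Applies the targeted rule and the AHA rule to the same cohort, labels
#' every participant against the duplex reference standard and returns
#' both accuracy reports side by side, mirroring the layout of a published
#' two-strategy results table.
#'
#' @param cohort validated cohort data.frame.
#' @param duplex duplex findings data.frame (or precomputed `labels`).
#' @param labels optional reference labels; computed from `duplex` when
#'   absent.
#' @param thresholds,conventions screening configuration.
#' @param conf_level confidence level for all intervals.
#' @param truncate_accuracy passed to [dx_accuracy()] (truncate the printed
#'   accuracy cell).
#' @param denominator_override optional accuracy denominator (e.g. the
#'   recruited N when exclusions shrank the analyzed set).
#' @return object of class `pad_comparison`: list of two [dx_accuracy()]
#'   reports plus decisions and exclusion logs.
#' @export
pad_compare <- function(cohort, duplex = NULL, labels = NULL,
                        thresholds = screening_thresholds(),
                        conventions = index_conventions(),
                        conf_level = 0.95, truncate_accuracy = FALSE,
                        denominator_override = NULL) {
  if (is.null(labels)) {
    stopifnot(!is.null(duplex))
    labels <- label_cohort(duplex, ids = cohort$id)
  }
  reports <- list()
  decisions <- list()
  exclusions <- list()
  for (strat in c("targeted", "aha")) {
    scr <- screen_cohort(cohort, strat, thresholds, conventions)
    bc <- build_contingency(scr$decisions, labels,
                            denominator_override = denominator_override)
    reports[[strat]] <- dx_accuracy(bc$table, strategy = strat,
                                    conf_level = conf_level,
                                    truncate_accuracy = truncate_accuracy,
                                    n_excluded = bc$n_excluded,
                                    n_indeterminate = bc$n_indeterminate)
    decisions[[strat]] <- scr$decisions
    exclusions[[strat]] <- scr$exclusions
  }
  structure(list(targeted = reports$targeted, aha = reports$aha,
                 decisions = decisions, exclusions = exclusions,
                 labels = labels),
            class = "pad_comparison")
}

#' @export
print.pad_comparison <- function(x, ...) {
  t_rows <- format_metric_rows(x$targeted)
  a_rows <- format_metric_rows(x$aha)
  tab <- cbind(t_rows, a_rows[, c("estimate", "ci")])
  names(tab) <- c("", "targeted", "95% CI", "AHA", "95% CI")
  cat("Screening strategy comparison\n")
  cat(sprintf("targeted: n=%d analyzed (%d excluded); AHA: n=%d analyzed (%d excluded)\n",
              x$targeted$n_analyzed, x$targeted$n_excluded,
              x$aha$n_analyzed, x$aha$n_excluded))
  out <- format(rbind(names(tab), as.matrix(tab)), justify = "left")
  cat(apply(out, 1, paste, collapse = "  "), sep = "\n")
  cat("(* important likelihood ratio, ~ may be important)\n")
  invisible(x)
}

#' @export
summary.pad_comparison <- function(object, ...) {
  print(object)
  invisible(list(targeted = object$targeted$metrics,
                 aha = object$aha$metrics))
}

#' @export
plot.pad_comparison <- function(x, ...) {
  sel <- c("sens", "spec", "ppv", "npv")
  mt <- x$targeted$metrics[x$targeted$metrics$metric %in% sel, ]
  ma <- x$aha$metrics[x$aha$metrics$metric %in% sel, ]
  at_t <- seq_along(sel) - 0.1
  at_a <- seq_along(sel) + 0.1
  graphics::plot(at_t, mt$estimate, xlim = c(0.5, length(sel) + 0.5),
                 ylim = c(0, 100), xaxt = "n", xlab = "", ylab = "%",
                 pch = 19, main = "Screening strategy comparison", ...)
  graphics::points(at_a, ma$estimate, pch = 1)
  graphics::segments(at_t, mt$ci_low, at_t, mt$ci_high)
  graphics::segments(at_a, ma$ci_low, at_a, ma$ci_high, lty = 2)
  graphics::axis(1, at = seq_along(sel), labels = sel)
  graphics::legend("bottomright", c("targeted", "AHA"), pch = c(19, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Run the full pipeline
#'
#' Loads (or simulates) a cohort, applies both strategies, evaluates each
#' against the reference standard and returns the comparison together with
#' a provenance log (package version, seed, configuration hash).
#'
#' @param config a [run_config()] object.
#' @param cohort_path,duplex_path CSVs to analyse; ignored when
#'   `simulate = TRUE`.
#' @param simulate generate the cohort from `config$simulation` instead of
#'   reading files.
#' @param seed seed for simulation (default the simulation block's).
#' @return list with `comparison` (a `pad_comparison`), `cohort`,
#'   `labels` and `log`.
#' @export
run_pipeline <- function(config = run_config(), cohort_path = NULL,
                         duplex_path = NULL, simulate = FALSE,
                         seed = config$simulation$seed) {
  if (simulate) {
    gen <- generate_cohort(config$simulation, seed = seed)
    cohort <- gen$cohort
    duplex <- gen$duplex
  } else {
    stopifnot(!is.null(cohort_path), !is.null(duplex_path))
    cohort <- read_cohort(cohort_path)
    duplex <- read_duplex(duplex_path)
  }
  cmp <- pad_compare(cohort, duplex,
                     thresholds = config$thresholds,
                     conventions = config$conventions,
                     conf_level = config$report$ci_level,
                     truncate_accuracy = config$report$rounding == "truncate",
                     denominator_override =
                       config$report$denominator_override)
  log <- list(package_version =
                as.character(utils::packageVersion("limbscreen")),
              seed = if (simulate) seed else NA,
              config_hash = config_hash(config),
              timestamp = format(Sys.time(), tz = "UTC"))
  list(comparison = cmp, cohort = cohort,
       labels = cmp$labels, log = log)
}

# md5 of the deparsed config; tools::md5sum needs a file
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
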