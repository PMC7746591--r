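#' Recompute the published study aggregates
#'
#' Runs the full analysis chain on the bundled data — threshold
#' classification, the 2x2 contingency table and exact test, the threshold
#' sweep, follow-up summaries, and the high-threshold risk fractions — and
#' returns each computed quantity next to its published counterpart with a
#' status flag.
#'
#' Statuses: `"match"` when the computed value reproduces the printed one at
#' its printed precision; `"known discrepancy"` for quantities affected by
#' the missing metastatic table row (the printed per-patient tables hold 17
#' metastatic patients where the published contingency counts hold 18, so
#' the high-group follow-up means/medians and several sweep rows cannot
#' recompute from the printed tables); `"mismatch"` otherwise. Quantities
#' that depend on the published contingency counts are computed from
#' [study_contingency_counts()]; quantities that depend on per-patient data
#' come from [bundled_study_cohort()].
#'
#' @return data.frame of class `cmc_reproduction` with columns `quantity`,
#'   `computed`, `published`, `status`.
#' @export
reproduce_paper <- function() {
  co <- bundled_study_cohort()
  tab4 <- study_contingency_counts()
  g <- classify_by_threshold(co, 2)
  low <- followup_summary(g$low)
  met_high <- g$high[g$high$metastasis, , drop = FALSE]
  non_high <- g$high[!g$high$metastasis, , drop = FALSE]
  met_sum <- followup_summary(met_high)
  non_sum <- followup_summary(non_high)
  r100 <- high_threshold_risk(co, 100)
  r200 <- high_threshold_risk(co, 200)
  p_fisher <- fisher_exact_two_tailed(tab4)
  overall_pct <- round_half_up(100 * (tab4$a + tab4$b) /
                                 (tab4$a + tab4$b + tab4$c + tab4$d), 1)
  high_pct <- round_half_up(100 * tab4$b / (tab4$b + tab4$d))

  row <- function(quantity, computed, published, status) {
    data.frame(quantity = quantity, computed = computed,
               published = published, status = status,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("low-group size (<=2 CMCs always)", nrow(g$low), 11,
        if (nrow(g$low) == 11) "match" else "mismatch"),
    row("low-group metastatic count", sum(g$low$metastasis), 0,
        if (sum(g$low$metastasis) == 0) "match" else "mismatch"),
    row("high-group size (>2 CMCs ever)", nrow(g$high), 27,
        if (nrow(g$high) == 27) "match" else "mismatch"),
    row("Fisher two-tailed p (contingency counts)", round_half_up(p_fisher, 4),
        0.0002,
        if (round_half_up(p_fisher, 4) == 0.0002) "match" else "mismatch"),
    row("high-group metastatic % (contingency counts)", high_pct, 67,
        if (high_pct == 67) "match" else "mismatch"),
    row("overall metastasis % (contingency counts)", overall_pct, 47.4,
        if (overall_pct == 47.4) "match" else "mismatch"),
    row("low-group mean follow-up (days)", low$mean_days, 1288,
        if (round_half_up(low$mean_days) == 1288) "match" else "mismatch"),
    row("low-group median follow-up (days)", low$median_days, 1186,
        if (low$median_days == 1186) "match" else "mismatch"),
    row(">100 CMC metastasis risk (%)", r100$pct_display, 71,
        if (identical(r100$pct_display, 71)) "match" else "mismatch"),
    row(">200 CMC metastasis risk (%)", r200$pct_display, 80,
        if (identical(r200$pct_display, 80)) "match" else "mismatch"),
    row("high-group metastatic count (patient tables)",
        sum(g$high$metastasis), 18,
        "known discrepancy (printed tables hold 17 metastatic rows, counts say 18)"),
    row("metastatic-group mean follow-up (days)",
        round_half_up(met_sum$mean_days, 1), 850,
        "known discrepancy (missing table row)"),
    row("metastatic-group median follow-up (days)", met_sum$median_days, 727,
        "known discrepancy (missing table row)"),
    row("nonmetastatic high-group mean follow-up (days)",
        round_half_up(non_sum$mean_days, 1), 728,
        "known discrepancy (missing table row)"),
    row("nonmetastatic high-group median follow-up (days)",
        non_sum$median_days, 495,
        "known discrepancy (missing table row)")
  )
  class(out) <- c("cmc_reproduction", "data.frame")
  out
}

#' @export
print.cmc_reproduction <- function(x, ...) {
  cat("Computed vs published study aggregates\n")
  print.data.frame(x, right = FALSE, row.names = FALSE)
  invisible(x)
}

.config_defaults <- list(
  droplet_volume = 1,
  sample_volume = 1000,
  flow_rate = 60,
  threshold_multiplier = 3,
  classification_threshold = 2
)

#' Load an analysis configuration
#'
#' Reads a YAML configuration and merges it over the package defaults
#' (droplet volume 1 microlitre, sample volume 1000 microlitres, flow rate
#' 60 microlitres/min, detection threshold multiplier 3, classification
#' threshold 2 CMCs/ml). Unknown keys are rejected by name so that typos
#' fail loudly rather than silently falling back to a default.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return named list of configuration values.
#' @export
run_config <- function(path = NULL) {
  cfg <- .config_defaults
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_cmc(sprintf("config file not found: %s", path), "cmcflow_io_error")
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop_cmc(sprintf("unknown config key(s): %s (valid keys: %s)",
                       paste(unknown, collapse = ", "),
                       paste(names(cfg), collapse = ", ")),
               "cmcflow_config_error")
    }
    cfg[names(user)] <- user
  }
  cfg
}
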