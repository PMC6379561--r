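#' Tidy dmrkit result objects
#'
#' `tidy()` methods return the per-feature table inside a result
#' object as a plain tibble: long window-by-sample counts for
#' `window_counts`, the DMR table for `dmr_set`, per-transcript
#' statistics for `de_result`, and per-animal consensus calls for
#' `disease_calls`.
#'
#' @param x A dmrkit result object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name tidy-dmrkit
NULL

#' One-row summaries of dmrkit result objects
#'
#' `glance()` methods return a one-row tibble of headline numbers:
#' totals for `window_counts`, DMR counts and parameters for
#' `dmr_set`, DE tallies for `de_result`, lineage disease frequencies
#' and the Fisher p-value for `disease_calls`, and the recovery
#' scorecard for `pipeline_result`.
#'
#' @param x A dmrkit result object.
#' @param ... Unused, for generic consistency.
#' @return A one-row tibble.
#' @name glance-dmrkit
NULL

#' Plot dmrkit result objects
#'
#' `autoplot()` methods give the standard display for each result
#' type: DMR feature histograms (`dmr_set`), differential-expression
#' tallies by RNA class and sncRNA subclass (`de_result`), and disease
#' frequency by lineage (`disease_calls`).
#'
#' @param object A dmrkit result object.
#' @param ... Unused, for generic consistency.
#' @return A ggplot object.
#' @name autoplot-dmrkit
NULL
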