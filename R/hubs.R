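#' Classify network hubs and their provincial/connector type
#'
#' A region is a hub when its degree, betweenness centrality and/or
#' clustering coefficient exceeds the network mean of that metric by more
#' than one standard deviation. Hubs are typed by participation coefficient:
#' connector when `P` exceeds `connector_threshold` (default 0.30, the
#' Guimera-Amaral taxonomy cut), provincial otherwise. A metric with zero
#' variance across regions can mark no hubs.
#'
#' @param metrics Tibble as produced by [node_metrics()] or
#'   [group_mean_metrics()] (columns `region`, `degree`, `clustering`,
#'   `betweenness`, `participation`).
#' @param connector_threshold Participation cut separating connector from
#'   provincial hubs.
#' @return Tibble with columns `region`, `is_hub`, `qualifying_criteria`
#'   (comma-joined subset of degree/betweenness/clustering), `hub_type`
#'   (`"connector"`, `"provincial"` or `"none"`) and `participation`.
#' @export
classify_hubs <- function(metrics, connector_threshold = 0.30) {
  needed <- c("region", "degree", "clustering", "betweenness", "participation")
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols) > 0) {
    abort(paste0("`metrics` lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "cc_config_error")
  }
  exceeds <- function(x) x > mean(x) + stats::sd(x)
  crit <- cbind(
    degree = exceeds(metrics$degree),
    betweenness = exceeds(metrics$betweenness),
    clustering = exceeds(metrics$clustering)
  )
  is_hub <- rowSums(crit) > 0
  qualifying <- apply(crit, 1, function(row) {
    paste(colnames(crit)[row], collapse = ",")
  })
  tibble(
    region = metrics$region,
    is_hub = is_hub,
    qualifying_criteria = qualifying,
    hub_type = dplyr::case_when(
      !is_hub ~ "none",
      metrics$participation > connector_threshold ~ "connector",
      TRUE ~ "provincial"
    ),
    participation = metrics$participation
  )
}
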