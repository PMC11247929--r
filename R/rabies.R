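#' Validate a traced-cell table
#'
#' Checks the schema of a rabies-tracing cell table: columns `region`,
#' `hemisphere` (`ipsi`/`contra`), `layer`, `gfp`, `mcherry`.  Starter cells
#' are GFP+ mCherry+; input cells are mCherry+ GFP-.
#'
#' @param table data.frame.
#' @return The table, invisibly, after validation.
#' @export
validate_traced_table <- function(table) {
  need <- c("region", "hemisphere", "layer", "gfp", "mcherry")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("traced-cell table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(table$hemisphere %in% c("ipsi", "contra")))
    stop("hemisphere must be 'ipsi' or 'contra'", call. = FALSE)
  if (!all(table$gfp %in% c(0, 1)) || !all(table$mcherry %in% c(0, 1)))
    stop("gfp and mcherry must be 0/1 flags", call. = FALSE)
  invisible(table)
}

is_input_cell <- function(table, include_starters = FALSE) {
  if (include_starters) table$mcherry == 1
  else table$mcherry == 1 & table$gfp == 0
}

#' Brain-wide input fractions
#'
#' Counts rabies-traced input cells (mCherry+ GFP-; starters excluded from
#' the denominator unless `include_starters = TRUE`) per region and
#' hemisphere, as a percentage of all input cells.  A region-hemisphere entry
#' is flagged `reported` only when its percentage strictly exceeds
#' `report_threshold_pct`.
#'
#' @param table traced-cell table (see [validate_traced_table()]).
#' @param report_threshold_pct reporting cut-off, percent (default 1;
#'   strict `>`).
#' @param include_starters also count starter cells in the denominator.
#' @return data.frame with `region`, `hemisphere`, `count`, `percent`,
#'   `reported`, sorted by decreasing percent.  Percentages sum to 100.
#' @export
input_fractions <- function(table, report_threshold_pct = 1,
                            include_starters = FALSE) {
  validate_traced_table(table)
  inputs <- table[is_input_cell(table, include_starters), , drop = FALSE]
  if (nrow(inputs) == 0)
    stop("empty tracing: no input cells in the table", call. = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(inputs))),
                          by = list(region = inputs$region,
                                    hemisphere = inputs$hemisphere),
                          FUN = sum)
  agg$percent <- 100 * agg$count / sum(agg$count)
  agg$reported <- agg$percent > report_threshold_pct
  agg[order(-agg$percent, agg$region), , drop = FALSE]
}

#' Starter-cell layer distribution
#'
#' Fractions of starter cells (GFP+ mCherry+) per cortical layer; fractions
#' sum to 1.
#'
#' @param table traced-cell table.
#' @return Named numeric vector of layer fractions.
#' @export
starter_layer_distribution <- function(table) {
  validate_traced_table(table)
  starters <- table[table$gfp == 1 & table$mcherry == 1, , drop = FALSE]
  if (nrow(starters) == 0)
    stop("no starter cells in the table", call. = FALSE)
  tab <- table(starters$layer)
  fr <- as.numeric(tab) / nrow(starters)
  names(fr) <- names(tab)
  fr
}

#' Local input layer fractions
#'
#' Fractions of local input cells (mCherry+ GFP- in the ipsilateral local
#' region, by default VISp) per cortical layer, normalized to the total
#' local-input count.  Contralateral cells of the same region are excluded.
#'
#' @param table traced-cell table.
#' @param local_region region label of the injection site (default "VISp").
#' @return Named numeric vector of layer fractions (sum 1).
#' @export
local_layer_fractions <- function(table, local_region = "VISp") {
  validate_traced_table(table)
  sel <- is_input_cell(table) & table$region == local_region &
    table$hemisphere == "ipsi"
  loc <- table[sel, , drop = FALSE]
  if (nrow(loc) == 0)
    stop(sprintf("no local input cells in region '%s'", local_region),
         call. = FALSE)
  tab <- table(loc$layer)
  fr <- as.numeric(tab) / nrow(loc)
  names(fr) <- names(tab)
  fr
}
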