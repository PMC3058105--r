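# Diagnosis count tables: the calibration currency. A count table is a
# data.frame over the full cell grid arm x detection mode (x stage group
# [x cell type]), with one `count` column holding observed integers or
# model-expected nonnegative reals.

ct_arms <- c("intervention", "control")
ct_modes <- c("screen_detected", "clinically_diagnosed")
ct_groups <- c("II_minus", "III_plus")

ct_strata <- c("marginal", "by_stage", "by_stage_and_celltype")

ct_grid <- function(stratification) {
  switch(stratification,
    marginal = expand.grid(arm = ct_arms, mode = ct_modes,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    by_stage = expand.grid(arm = ct_arms, mode = ct_modes, stage_group = ct_groups,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    by_stage_and_celltype = expand.grid(arm = ct_arms, mode = ct_modes,
                                        stage_group = ct_groups, cell_type = cell_types(),
                                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
}

ct_keys <- function(stratification) {
  switch(stratification,
    marginal = c("arm", "mode"),
    by_stage = c("arm", "mode", "stage_group"),
    by_stage_and_celltype = c("arm", "mode", "stage_group", "cell_type"))
}

#' Diagnosis count table
#'
#' Builds a canonical count table over the full cell grid for the requested
#' stratification. Cells absent from `cells` are zero. Observed tables carry
#' nonnegative integers; expected tables carry nonnegative reals.
#'
#' @param cells data.frame with key columns (`arm`, `mode`, optionally
#'   `stage_group`, `cell_type`) and a `count` column.
#' @param stratification one of `"marginal"`, `"by_stage"`,
#'   `"by_stage_and_celltype"`; inferred from the columns of `cells` when
#'   `NULL`.
#' @return data.frame of class `count_table`, rows in canonical cell order,
#'   with attribute `stratification`.
#' @export
count_table <- function(cells, stratification = NULL) {
  stopifnot(is.data.frame(cells), "count" %in% names(cells))
  if (is.null(stratification)) {
    stratification <- if ("cell_type" %in% names(cells)) "by_stage_and_celltype"
    else if ("stage_group" %in% names(cells)) "by_stage" else "marginal"
  }
  stratification <- match.arg(stratification, ct_strata)
  keys <- ct_keys(stratification)
  if (!all(keys %in% names(cells)))
    stop("cells must have columns: ", paste(keys, collapse = ", "))
  if (!all(cells$arm %in% ct_arms)) stop("arm must be one of: ", paste(ct_arms, collapse = ", "))
  if (!all(cells$mode %in% ct_modes)) stop("mode must be one of: ", paste(ct_modes, collapse = ", "))
  if ("stage_group" %in% keys && !all(cells$stage_group %in% ct_groups))
    stop("stage_group must be one of: ", paste(ct_groups, collapse = ", "))
  if ("cell_type" %in% keys && !all(cells$cell_type %in% cell_types()))
    stop("cell_type must be one of: ", paste(cell_types(), collapse = ", "))
  if (any(!is.finite(cells$count)) || any(cells$count < 0))
    stop("counts must be finite and nonnegative")
  grid <- ct_grid(stratification)
  agg <- stats::aggregate(cells$count, by = cells[keys], FUN = sum)
  names(agg)[ncol(agg)] <- "count"
  out <- merge(grid, agg, by = keys, all.x = TRUE, sort = FALSE)
  out$count[is.na(out$count)] <- 0
  key <- do.call(paste, c(out[keys], sep = "\r"))
  ord <- match(do.call(paste, c(grid[keys], sep = "\r")), key)
  out <- out[ord, c(keys, "count")]
  rownames(out) <- NULL
  structure(out, stratification = stratification,
            class = c("count_table", "data.frame"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("Diagnosis count table (%s stratification)\n", attr(x, "stratification")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Collapse a count table to a coarser stratification
#'
#' @param ct a [count_table()].
#' @param stratification target level, at most as fine as the input's.
#' @return A [count_table()] at the requested level.
#' @export
aggregate_counts <- function(ct, stratification = "marginal") {
  stopifnot(inherits(ct, "count_table"))
  stratification <- match.arg(stratification, ct_strata)
  have <- attr(ct, "stratification")
  if (match(stratification, ct_strata) > match(have, ct_strata))
    stop("cannot refine a ", have, " table to ", stratification)
  count_table(as.data.frame(ct), stratification)
}

same_layout <- function(a, b) {
  identical(attr(a, "stratification"), attr(b, "stratification")) &&
    nrow(a) == nrow(b) &&
    identical(a[ct_keys(attr(a, "stratification"))],
              b[ct_keys(attr(b, "stratification"))])
}

#' Read and write count tables as CSV
#'
#' Plain CSV with the key columns and `count`; extra columns (such as a
#' `source` annotation) are preserved on write and ignored on read.
#'
#' @param path file path.
#' @param ct a [count_table()].
#' @return `read_count_table` returns a [count_table()]; `write_count_table`
#'   returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  count_table(d)
}

#' @rdname read_count_table
#' @export
write_count_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
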