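#' @name panel
#' @title Long-format panel data conventions
#' @description Panels are plain data.frames in long format with columns
#'   `id`, `time`, manifest indicators `y1..yp`, covariates `x1..xr`
#'   (binary or continuous), and fully observed auxiliaries `z1..zs`.
#'   Missing values are `NA`. Time indices must be consecutive within
#'   person. Functions that mask data keep the pre-mask panel in the
#'   `"truth"` attribute so that evaluation code can recover masked values.
NULL

panel_vars <- function(panel) {
  nm <- names(panel)
  list(y = grep("^y[0-9]+$", nm, value = TRUE),
       x = grep("^x[0-9]+$", nm, value = TRUE),
       z = grep("^z[0-9]+$", nm, value = TRUE),
       R = grep("^R_", nm, value = TRUE))
}

validate_panel <- function(panel) {
  stopifnot(all(c("id", "time") %in% names(panel)))
  ord <- order(panel$id, panel$time)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    panel <- panel[ord, , drop = FALSE]
    rownames(panel) <- NULL
  }
  bad <- unlist(lapply(split(panel$time, panel$id), function(tt) {
    any(diff(tt) != 1L) || tt[1] < 1L
  }))
  if (any(bad)) {
    stop("time indices not consecutive within person(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  pv <- panel_vars(panel)
  if (length(pv$z) && anyNA(panel[pv$z])) {
    stop("auxiliary (z) columns must be fully observed")
  }
  panel
}

panel_missing_mask <- function(panel) {
  pv <- panel_vars(panel)
  is.na(as.matrix(panel[c(pv$y, pv$x)]))
}

# person index bookkeeping for the compiled recursions (0-based starts)
panel_index <- function(panel) {
  ids <- unique(panel$id)
  len <- as.integer(table(factor(panel$id, levels = ids)))
  start <- cumsum(c(0L, len[-length(len)]))
  list(ids = ids, start = as.integer(start), len = len)
}

#' Missingness rates and simultaneity diagnostics of a panel
#'
#' @param panel a long-format panel.
#' @return list with `rates` (per-variable empirical missing proportion),
#'   `simultaneous` (per-occasion counts of the number of missing y/x
#'   entries, tabulated), and `n` (occasions).
#' @export
missingness_summary <- function(panel) {
  panel <- validate_panel(panel)
  pv <- panel_vars(panel)
  M <- panel_missing_mask(panel)
  list(rates = colMeans(M),
       simultaneous = table(rowSums(M)),
       n = nrow(panel))
}
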