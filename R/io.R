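# Long-format CSV I/O. Dialect: header id,time,y1..yp,x1..xr,z1..zs
# [,R_*], one row per (person, occasion), empty field or "NA" as the
# missing sentinel. Lines starting with '#' are metadata comments.

#' Read a long-format panel CSV
#'
#' @param path file path.
#' @return validated panel data.frame.
#' @export
read_panel_csv <- function(path) {
  dat <- utils::read.csv(path, comment.char = "#",
                         na.strings = c("NA", ""))
  nm <- names(dat)
  if (!identical(nm[1:2], c("id", "time"))) {
    stop("header must start with id,time")
  }
  known <- grepl("^(y|x|z)[0-9]+$|^R_", nm[-(1:2)])
  if (any(!known)) {
    stop("unknown column(s): ", paste(nm[-(1:2)][!known], collapse = ", "))
  }
  validate_panel(dat)
}

#' Write a panel to long-format CSV
#'
#' @param panel panel data.frame.
#' @param path file path.
#' @param indicators also write `R_<var>` missingness indicator columns.
#' @param header optional named character/numeric vector written as
#'   `# key=value` comment lines (e.g. seed, config hash).
#' @return invisibly, the path.
#' @export
write_panel_csv <- function(panel, path, indicators = FALSE,
                            header = NULL) {
  out <- as.data.frame(panel)
  attr(out, "truth") <- NULL
  if (indicators) {
    pv <- panel_vars(out)
    for (v in c(pv$y, pv$x)) {
      out[[paste0("R_", v)]] <- as.integer(is.na(out[[v]]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", names(header), "=", unname(header)), con)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write latent paths to CSV (id, time, factor, estimate, variance)
#'
#' @param latent a latent-paths data.frame (with optional covariance
#'   attribute providing per-occasion variances).
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_latent_csv <- function(latent, path) {
  eta_cols <- grep("^eta[0-9]+$", names(latent), value = TRUE)
  cv <- attr(latent, "cov")
  rows <- lapply(seq_along(eta_cols), function(j) {
    data.frame(id = latent$id, time = latent$time, factor = j,
               estimate = latent[[eta_cols[j]]],
               variance = if (!is.null(cv)) cv[j, j, ] else 0)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$time, out$factor), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic small test fixture
#'
#' A 4-person x 12-occasion panel simulated from the low-autocorrelation
#' PFA preset with calibrated factor-dependent masking. Used by the unit
#' tests; regeneration with the same seed is bitwise identical.
#'
#' @param seed fixture seed (fixed default).
#' @return masked panel (truth attribute retained).
#' @export
make_fixture <- function(seed = 20240712L) {
  template <- pfa_template("low")
  sim <- simulate_panel(template, n_persons = 4, n_times = 12, seed = seed)
  spec <- calibrate_phi0(missingness_spec("factor_dependent"),
                         params = template)
  apply_factor_dependent(sim$panel, sim$latent, spec, seed = seed + 1L)
}
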