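#' Read isotropic shieldings from a MAGRES file
#'
#' Parses the `ms` (magnetic shielding) lines of a MAGRES file (the
#' `[magres]` block written by plane-wave DFT codes): each line carries an
#' atom species label, an index, and the nine Cartesian components of the
#' shielding tensor. The isotropic shielding is the tensor trace divided
#' by three.
#'
#' @param path path to a MAGRES file.
#' @return data.frame with columns `atom_label` (species + index),
#'   `element`, `sigma_iso` (ppm). Empty with a warning if the file has no
#'   `ms` records.
#' @export
read_magres <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # restrict to the [magres] block when the tags are present
  open <- grep("^\\s*\\[magres\\]", lines)
  close <- grep("^\\s*\\[/magres\\]", lines)
  if (length(open) && length(close)) lines_ms <- lines[(open[1] + 1):(close[1] - 1)]
  else lines_ms <- lines
  idx <- grep("^\\s*ms\\s", lines_ms)
  if (!length(idx)) {
    warning("no ms records found in ", path)
    return(data.frame(atom_label = character(), element = character(),
                      sigma_iso = numeric()))
  }
  recs <- lapply(idx, function(i) {
    tok <- strsplit(trimws(lines_ms[i]), "\\s+")[[1]]
    if (length(tok) != 12)
      stop_invalid("malformed ms record at line %d: expected 'ms label index + 9 tensor components', got %d fields",
                   i, length(tok))
    vals <- suppressWarnings(as.numeric(tok[4:12]))
    if (any(is.na(vals)))
      stop_invalid("non-numeric tensor component in ms record at line %d", i)
    data.frame(atom_label = paste0(tok[2], tok[3]),
               element = gsub("[0-9]+$", "", tok[2]),
               sigma_iso = (vals[1] + vals[5] + vals[9]) / 3)
  })
  out <- do.call(rbind, recs)
  if (anyDuplicated(out$atom_label))
    stop_invalid("duplicate atom labels in %s", path)
  rownames(out) <- NULL
  out
}

#' Regress experimental shifts on computed shieldings
#'
#' Ordinary least squares of the experimental chemical shift on the
#' computed isotropic shielding, fitted separately per element. The
#' residual standard deviation uses `n - 2` degrees of freedom and the
#' adjusted R^2 is `1 - (1 - R^2) (n - 1) / (n - 2)`. With
#' `fixed_slope = TRUE` the slope is constrained to -1 (pure referencing:
#' `delta = sigma_ref - sigma`) and only the intercept is estimated.
#'
#' @param sigma_iso computed isotropic shieldings, ppm.
#' @param delta_exp experimental shifts, ppm, same length.
#' @param element element label stored in the result.
#' @param fixed_slope constrain the slope to -1.
#' @return object of class `shift_model`: list with `slope`, `intercept`
#'   (ppm), `resid_sd` (ppm), `adj_r2`, `n`, `element`, `fit`.
#' @export
fit_shift_model <- function(sigma_iso, delta_exp, element = "C", fixed_slope = FALSE) {
  if (length(sigma_iso) != length(delta_exp))
    stop_invalid("sigma_iso and delta_exp differ in length")
  n <- length(sigma_iso)
  if (n < 3) stop_invalid("need at least 3 shielding/shift pairs")
  if (diff(range(sigma_iso)) == 0)
    stop_invalid("shieldings are constant; regression is rank-deficient")
  if (fixed_slope) {
    intercept <- mean(delta_exp + sigma_iso)
    resid <- delta_exp - (intercept - sigma_iso)
    resid_sd <- sqrt(sum(resid^2) / (n - 1))
    sst <- sum((delta_exp - mean(delta_exp))^2)
    r2 <- 1 - sum(resid^2) / sst
    adj <- 1 - (1 - r2) * (n - 1) / (n - 1)  # one parameter estimated
    fit <- NULL
    slope <- -1
  } else {
    fit <- stats::lm(delta_exp ~ sigma_iso)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    resid_sd <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
    r2 <- suppressWarnings(summary(fit))$r.squared
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  }
  structure(list(slope = slope, intercept = intercept, resid_sd = resid_sd,
                 adj_r2 = adj, n = n, element = element, fit = fit),
            class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("<shift_model> %s: delta = %.4f * sigma + %.2f ppm, resid sd %.3g ppm, adj R^2 %.5f, n = %d\n",
              x$element, x$slope, x$intercept, x$resid_sd, x$adj_r2, x$n))
  invisible(x)
}

#' Predict chemical shifts from shieldings
#'
#' Applies a fitted [fit_shift_model()] to shielding records and, when
#' experimental shifts are supplied, returns the residual table for
#' outlier inspection.
#'
#' @param records data.frame with at least `sigma_iso` and optionally
#'   `element` columns (as from [read_magres()]), or a numeric vector of
#'   shieldings.
#' @param model a `shift_model`.
#' @param delta_exp optional experimental shifts for residuals.
#' @return data.frame with `sigma_iso`, `delta_pred` and, when available,
#'   `delta_exp`, `residual`.
#' @export
predict_shifts <- function(records, model, delta_exp = NULL) {
  stopifnot(inherits(model, "shift_model"))
  if (is.numeric(records)) records <- data.frame(sigma_iso = records)
  if ("element" %in% names(records)) {
    bad <- records$element != model$element
    if (any(bad))
      stop_invalid("records contain element(s) %s but the model is for %s",
                   paste(unique(records$element[bad]), collapse = ","), model$element)
  }
  out <- data.frame(sigma_iso = records$sigma_iso,
                    delta_pred = model$slope * records$sigma_iso + model$intercept)
  if ("atom_label" %in% names(records)) out <- cbind(atom_label = records$atom_label, out)
  if (!is.null(delta_exp)) {
    out$delta_exp <- delta_exp
    out$residual <- delta_exp - out$delta_pred
  }
  out
}
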