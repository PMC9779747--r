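# Cross-method comparison arithmetic: dilution-consistency ratios,
# replicate errors (largest deviation from the mean), within-error
# agreement tallies, and emission of the per-sample summary tables.

#' Round half-up for table display
#'
#' Commercial-rounding variant used for displayed ratios (base R's
#' `round()` rounds half to even). A 1e-9 guard absorbs binary
#' representation error, so decimal literals sitting on a half boundary
#' (e.g. 1.265, stored slightly below) round up as intended.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(1.265, 2)  # 1.27
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Dilution-consistency ratio
#'
#' Ratio of two dilution-corrected measurements of the same sample at two
#' dilutions (conventionally higher dilution over lower). If the
#' correction is consistent the ratio is ideally 1.
#'
#' @param value_high Dilution-corrected quantity at the higher dilution.
#' @param value_low Dilution-corrected quantity at the lower dilution.
#'
#' @return The full-precision ratio, with a `display` attribute holding
#'   the half-up 2-decimal rendering used in tables.
#' @examples
#' dilution_ratio(9.7e13, 1.1e14)  # displays as 0.88
#' @export
dilution_ratio <- function(value_high, value_low) {
  if (!is.numeric(value_high) || !is.numeric(value_low) ||
      any(value_high <= 0) || any(value_low <= 0)) {
    stop("both values must be > 0", call. = FALSE)
  }
  r <- value_high / value_low
  attr(r, "display") <- round_half_up(r, 2L)
  r
}

#' Replicate error as the largest deviation from the mean
#'
#' For n >= 2 replicate measurements, reports the mean, the maximum
#' absolute deviation from the mean, and that deviation as a percentage
#' of the mean.
#'
#' @param values Numeric vector of replicate measurements (n >= 2).
#'
#' @return An object of class `scp_replicate_error`: list with `mean`,
#'   `max_abs_deviation`, `percent` (`NA` with a flag when the mean is 0),
#'   `n`.
#' @examples
#' replicate_error(c(10, 12, 14))  # mean 12, deviation 2, 16.7%
#' @export
replicate_error <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("at least 2 finite replicate values are required", call. = FALSE)
  }
  m <- mean(values)
  dev <- max(abs(values - m))
  pct <- if (m == 0) NA_real_ else 100 * dev / m
  structure(
    list(mean = m, max_abs_deviation = dev, percent = pct,
         n = length(values),
         flag = if (m == 0) "zero-mean" else NA_character_),
    class = "scp_replicate_error"
  )
}

#' @export
print.scp_replicate_error <- function(x, ...) {
  cat(sprintf("<replicate error> mean %.4g, max deviation %.4g (%s%%), n = %d\n",
              x$mean, x$max_abs_deviation,
              if (is.na(x$percent)) "NA" else sprintf("%.1f", x$percent),
              x$n))
  invisible(x)
}

#' Agreement of two measurements within their combined error
#'
#' TRUE when |a - b| <= err_a + err_b. Symmetric in the two measurements.
#'
#' @param rh_a,err_a First measurement and its error (same units).
#' @param rh_b,err_b Second measurement and its error.
#' @return Logical (vectorized).
#' @examples
#' agreement_within_error(100, 10, 108, 5)  # TRUE
#' @export
agreement_within_error <- function(rh_a, err_a, rh_b, err_b) {
  if (any(err_a < 0) || any(err_b < 0)) {
    stop("errors must be >= 0", call. = FALSE)
  }
  abs(rh_a - rh_b) <= err_a + err_b
}

#' Tally within-error agreement over paired measurements
#'
#' @param pairs A data.frame with columns `rh_a`, `err_a`, `rh_b`,
#'   `err_b` (one row per sample).
#' @return List with `n_agree`, `n_total`, and the per-row logical
#'   `agree`.
#' @export
agreement_tally <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("rh_a", "err_a", "rh_b", "err_b") %in% names(pairs)))
  agree <- agreement_within_error(pairs$rh_a, pairs$err_a,
                                  pairs$rh_b, pairs$err_b)
  list(n_agree = sum(agree), n_total = nrow(pairs), agree = agree)
}

#' Emit per-sample summary tables
#'
#' Writes up to four TSV files mirroring the layouts of multi-method
#' characterization reports: per-sample counts/radii from nanotracking,
#' DLS peak tables, dilution-consistency ratios, and replicate errors.
#' Missing inputs yield header-only files; missing cells are emitted
#' empty. Idempotent.
#'
#' @param ilm Data.frame as from [ilm_result_table()], or `NULL`.
#' @param dls Data.frame of DLS peak rows with columns `sample`,
#'   `rh_small_nm`, `frac_small`, `rh_main_nm`, `frac_main`,
#'   `rh_large_nm`, `frac_large`, `lp` (any subset; missing columns are
#'   emitted empty), or `NULL`.
#' @param ratios Data.frame with columns `sample`, `method`,
#'   `value_high`, `value_low` (ratio and display computed here), or
#'   `NULL`.
#' @param replicates Data.frame with columns `sample`, `quantity` and one
#'   replicate per column `rep1`, `rep2`, ... , or `NULL`.
#' @param out_dir Output directory (created if needed).
#'
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_summary_tables <- function(ilm = NULL, dls = NULL, ratios = NULL,
                                replicates = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ilm = file.path(out_dir, "ilm_summary.tsv"),
             dls = file.path(out_dir, "dls_peaks.tsv"),
             ratios = file.path(out_dir, "dilution_ratios.tsv"),
             replicates = file.path(out_dir, "replicate_errors.tsv"))
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
  }

  ilm_cols <- c("sample", "dilution", "n_tracked", "mean_rh_nm",
                "sd_rh_nm", "density_per_ml", "flags")
  ilm <- .conform(ilm, ilm_cols)
  wt(ilm, paths[["ilm"]])

  dls_cols <- c("sample", "rh_small_nm", "frac_small", "rh_main_nm",
                "frac_main", "rh_large_nm", "frac_large", "lp")
  dls <- .conform(dls, dls_cols)
  wt(dls, paths[["dls"]])

  if (is.null(ratios) || !nrow(ratios)) {
    rat <- .conform(NULL, c("sample", "method", "value_high", "value_low",
                            "ratio", "display"))
  } else {
    rat <- .conform(ratios, c("sample", "method", "value_high",
                              "value_low"))
    rat$ratio <- rat$value_high / rat$value_low
    rat$display <- round_half_up(rat$ratio, 2L)
  }
  wt(rat, paths[["ratios"]])

  if (is.null(replicates) || !nrow(replicates)) {
    rep_out <- .conform(NULL, c("sample", "quantity", "mean",
                                "max_abs_deviation", "percent"))
  } else {
    rep_cols <- grep("^rep", names(replicates), value = TRUE)
    rep_out <- do.call(rbind, lapply(seq_len(nrow(replicates)),
      function(i) {
        vals <- as.numeric(replicates[i, rep_cols])
        vals <- vals[is.finite(vals)]
        err <- replicate_error(vals)
        data.frame(sample = replicates$sample[i],
                   quantity = replicates$quantity[i],
                   mean = err$mean,
                   max_abs_deviation = err$max_abs_deviation,
                   percent = err$percent)
      }))
  }
  wt(rep_out, paths[["replicates"]])
  invisible(paths)
}

# pad/align a data.frame to a fixed column layout, warning on label-free
# extra columns; NULL yields a header-only frame
.conform <- function(df, cols) {
  if (is.null(df) || !nrow(df)) {
    out <- as.data.frame(rep(list(character(0)), length(cols)))
    names(out) <- cols
    return(out)
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    for (mc in missing_cols) df[[mc]] <- NA
  }
  df[, cols, drop = FALSE]
}
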