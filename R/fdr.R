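#' Target-decoy FDR estimation for cross-link spectrum matches
#'
#' Scans score thresholds over the CSM list and estimates the false discovery
#' rate with the standard cross-link target-decoy accounting
#' `FDR(t) = (TD(t) - DD(t)) / TT(t)`, floored at 0 and capped at 1; the
#' q-value is the running minimum of FDR over decreasing score. Single-sided
#' CSMs (class `NA`) are excluded.
#'
#' @param csms A CSM tibble with a `class` column (`TT`/`TD`/`DD`).
#' @param level `"csm"` (default) or `"linkage"` (group-wise on the best CSM
#'   score per residue pair; requires protein mappings in the CSMs).
#' @return A `kcx_fdr` object: list with `csms` (the scored rows plus `fdr`
#'   and `q` columns, sorted by decreasing score) and `level`. Use [tidy()]
#'   for the threshold table, [glance()] for a one-row summary, and
#'   [apply_fdr()] to filter.
#' @export
estimate_fdr <- function(csms, level = c("csm", "linkage")) {
  level <- match.arg(level)
  if (!"class" %in% names(csms) || all(is.na(csms$class))) {
    rlang::abort("CSMs carry no target/decoy classes; FDR is undefined without decoys")
  }
  x <- dplyr::filter(csms, !is.na(.data$class))
  if (level == "linkage") {
    x <- dplyr::mutate(x, .link_key = paste(
      purrr::map_chr(.data$alpha_proteins, function(p)
        if (is.null(p)) NA_character_ else sort(p$protein)[1]),
      .data$alpha_site, .data$beta_peptide, .data$beta_site, sep = "|"
    ))
    x <- dplyr::arrange(x, dplyr::desc(.data$score))
    x <- dplyr::distinct(x, .data$.link_key, .keep_all = TRUE)
    x$.link_key <- NULL
  }
  x <- dplyr::arrange(x, dplyr::desc(.data$score), abs(.data$prec_err_ppm))
  tt <- cumsum(x$class == "TT")
  td <- cumsum(x$class == "TD")
  dd <- cumsum(x$class == "DD")
  x$fdr <- pmin(1, pmax(0, td - dd) / pmax(tt, 1))
  x$fdr[tt == 0] <- 1
  x$q <- rev(cummin(rev(x$fdr)))
  structure(list(csms = x, level = level), class = "kcx_fdr")
}

#' @export
print.kcx_fdr <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<kcx_fdr> level=%s  %d matches (TT %d / TD %d / DD %d), %d at q<=0.01\n",
              x$level, g$n, g$n_tt, g$n_td, g$n_dd, g$n_q01))
  invisible(x)
}

#' @rdname estimate_fdr
#' @param x A `kcx_fdr` object.
#' @param ... Unused.
#' @export
tidy.kcx_fdr <- function(x, ...) {
  dplyr::select(x$csms, "scan", "score", "class", "fdr", "q")
}

#' @rdname estimate_fdr
#' @export
glance.kcx_fdr <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    n = nrow(x$csms),
    n_tt = sum(x$csms$class == "TT"),
    n_td = sum(x$csms$class == "TD"),
    n_dd = sum(x$csms$class == "DD"),
    n_q01 = sum(x$csms$q <= 0.01 & x$csms$class == "TT")
  )
}

#' Filter CSMs at a requested FDR
#'
#' @param fdr_result A `kcx_fdr` object.
#' @param fdr Requested FDR (default 0.01).
#' @return The retained target (TT) CSM tibble with `q` values.
#' @export
apply_fdr <- function(fdr_result, fdr = 0.01) {
  stopifnot(inherits(fdr_result, "kcx_fdr"))
  dplyr::filter(fdr_result$csms, .data$q <= fdr, .data$class == "TT")
}
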