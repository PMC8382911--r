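#' Acidic/basic residue ratio (DE/KR)
#'
#' The count of aspartate plus glutamate divided by the count of lysine plus
#' arginine, the standard sequence-level signature of halophilic
#' ("salt-in") proteomes; values above 2 mark strong acidic enrichment.
#' Gaps are ignored.
#'
#' @param sequence Character vector of residues or a single string.
#' @return Positive ratio; `Inf` if the sequence has acidic but no basic
#'   residues. A sequence with no charged residues is an error.
#' @export
de_kr_ratio <- function(sequence) {
  s <- if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    strsplit(toupper(sequence), "")[[1]] else toupper(sequence)
  s <- s[s != "-"]
  if (!length(s)) stop("empty sequence")
  num <- sum(s %in% c("D", "E"))
  den <- sum(s %in% c("K", "R"))
  if (num == 0 && den == 0) stop("sequence has no charged residues")
  if (den == 0) return(Inf)
  num / den
}

#' Fit the salt-stability transition midpoint
#'
#' Least-squares fit of the two-parameter logistic
#' `f(c) = 1 / (1 + exp(-(c - m) / w))` to a folded-fraction transition
#' curve; `m` is the midpoint (the salt concentration at which half the
#' protein remains folded and active) and `w` the transition width.
#' Initialization: `m` at the concentration whose fraction is nearest 0.5,
#' `w = (c_max - c_min) / 10`. If the optimizer fails, the 0.5 crossing is
#' estimated by linear interpolation instead (flagged in the result).
#'
#' For bell-shaped curves (e.g. MgCl2), restrict the fit to the
#' low-concentration limb with `window`.
#'
#' @param curve A [simulate_stability_curve()] object or data frame with
#'   columns `concentration` and `fraction`.
#' @param window Optional `c(min, max)` concentration window to fit within.
#' @return An object of class `mf_fit`: list with `mf_half`, `width`, `rss`,
#'   `converged`, `method` (`"logistic"` or `"interpolation"`) and `n`.
#' @export
fit_mf_half <- function(curve, window = NULL) {
  df <- as.data.frame(curve)[, c("concentration", "fraction")]
  if (!is.null(window))
    df <- df[df$concentration >= window[1] & df$concentration <= window[2], ]
  if (nrow(df) < 4) stop("at least 4 points are required")
  if (any(df$fraction < 0 | df$fraction > 1))
    stop("fractions must lie in [0, 1]")
  cc <- df$concentration; ff <- df$fraction
  m0 <- cc[which.min(abs(ff - 0.5))]
  w0 <- (max(cc) - min(cc)) / 10
  fit1 <- tryCatch(
    minpack.lm::nlsLM(fraction ~ 1 / (1 + exp(-(concentration - m) / w)),
                      data = df, start = list(m = m0, w = w0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # a sharp transition can defeat the prescribed start; retry from a
  # deterministic grid of widths and keep the best residual
  best <- fit1
  best_rss <- if (is.null(fit1)) Inf else sum(stats::resid(fit1)^2)
  if (best_rss > 1e-10) {
    for (w_try in c(w0 / 4, w0 / 16, w0 * 4)) {
      f <- tryCatch(
        minpack.lm::nlsLM(fraction ~ 1 / (1 + exp(-(concentration - m) / w)),
                          data = df, start = list(m = m0, w = w_try),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f) && sum(stats::resid(f)^2) < best_rss - 1e-14) {
        best <- f; best_rss <- sum(stats::resid(f)^2)
      }
    }
  }
  if (!is.null(best)) {
    est <- stats::coef(best)
    return(structure(list(mf_half = unname(est["m"]), width = unname(est["w"]),
                          rss = best_rss, converged = TRUE,
                          method = "logistic", n = nrow(df)),
                     class = "mf_fit"))
  }
  # fallback: first linear-interpolation crossing of 0.5
  idx <- which(diff(sign(ff - 0.5)) != 0)
  if (!length(idx)) stop("curve never crosses 0.5; cannot estimate midpoint")
  i <- idx[1]
  m_int <- cc[i] + (0.5 - ff[i]) * (cc[i + 1] - cc[i]) / (ff[i + 1] - ff[i])
  structure(list(mf_half = m_int, width = NA_real_, rss = NA_real_,
                 converged = FALSE, method = "interpolation", n = nrow(df)),
            class = "mf_fit")
}

#' @export
print.mf_fit <- function(x, ...) {
  cat("M^f1/2 =", format(x$mf_half), "M (width", format(x$width),
      "M;", x$method, "fit; rss", format(x$rss), ")\n")
  invisible(x)
}

#' Assemble a metric-vs-replacement trajectory table
#'
#' For a lineage of enzymes (ancestral nodes and extant taxa), computes each
#' enzyme's cumulative replacement count against the root ancestor
#' ([count_replacements()]) and joins the supplied per-enzyme metric values,
#' producing the table behind midpoint-vs-replacements trajectory plots.
#'
#' @param root_ancestor Root ancestral sequence (string or vector).
#' @param chain Named list of sequences (enzyme id -> sequence), ordered
#'   along the lineage.
#' @param metrics Data frame with columns `enzyme`, `metric`, `value` and
#'   optionally `salt`.
#' @return Data frame (class `trajectory_table`) with columns `enzyme`,
#'   `replacements`, `metric`, `value`, `salt`.
#' @export
build_trajectory <- function(root_ancestor, chain, metrics) {
  if (is.null(names(chain)) || any(!nzchar(names(chain))))
    stop("chain must be a named list of sequences")
  if (!all(c("enzyme", "metric", "value") %in% names(metrics)))
    stop("metrics needs columns enzyme, metric, value")
  if (is.null(metrics$salt)) metrics$salt <- NA_character_
  repl <- vapply(chain, function(s) count_replacements(root_ancestor, s),
                 numeric(1))
  rows <- metrics[metrics$enzyme %in% names(chain), , drop = FALSE]
  key <- paste(rows$enzyme, rows$metric, rows$salt)
  if (anyDuplicated(key))
    stop("duplicate (enzyme, metric, salt) rows in metrics")
  out <- data.frame(enzyme = rows$enzyme,
                    replacements = repl[rows$enzyme],
                    metric = rows$metric, value = rows$value,
                    salt = rows$salt, row.names = NULL)
  out <- out[order(match(out$enzyme, names(chain))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trajectory_table", "data.frame")
  out
}
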