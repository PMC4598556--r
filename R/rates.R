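#' Method-of-moments net diversification rate from stem age
#'
#' Closed-form estimator of a clade's net diversification rate (speciation
#' minus extinction, lineages/Myr) from its described species richness `n`
#' and stem age `t`, under an assumed relative extinction fraction
#' `epsilon` = extinction/speciation:
#'
#'   r = log(n * (1 - epsilon) + epsilon) / t
#'
#' Natural logarithm throughout. With `epsilon = 0` this reduces to
#' `log(n) / t`; a monotypic clade (`n = 1`) has rate 0 for any `epsilon`.
#'
#' @param n species richness, integer-valued, >= 1. Vectorized.
#' @param t stem age in Myr, > 0. Vectorized.
#' @param epsilon relative extinction fraction in \[0, 1). Vectorized.
#' @return net diversification rate(s), lineages/Myr.
#' @examples
#' mom_stem_rate(100, 50)            # log(100)/50
#' mom_stem_rate(1000, 100, 0.9)     # log(100.9)/100
#' @export
mom_stem_rate <- function(n, t, epsilon = 0) {
  if (!is.numeric(n) || anyNA(n) || any(n < 1))
    stop("'n' must be numeric species richness >= 1")
  if (!is.numeric(t) || anyNA(t) || any(t <= 0))
    stop("'t' must be a positive stem age in Myr")
  if (!is.numeric(epsilon) || anyNA(epsilon) ||
      any(epsilon < 0) || any(epsilon >= 1))
    stop("'epsilon' must be in [0, 1)")
  log(n * (1 - epsilon) + epsilon) / t
}

#' Diversification-rate table for a set of clades
#'
#' Applies [mom_stem_rate()] to every clade under each relative extinction
#' fraction. Clades with missing or invalid richness or stem age are
#' excluded with a logged reason (mirroring the exclusion of taxa with
#' unknown data from comparative analyses), not an error.
#'
#' @param records data frame with columns `clade_id`, `richness`,
#'   `stem_age_myr` (extra columns are ignored).
#' @param epsilon numeric vector of relative extinction fractions; the
#'   canonical set is `c(0, 0.5, 0.9)`.
#' @param quiet suppress exclusion messages.
#' @return data frame with one row per clade x epsilon: `clade_id`,
#'   `richness`, `stem_age_myr`, `epsilon`, `rate`. The excluded clades
#'   (if any) are attached as attribute `"excluded"`.
#' @export
rate_table <- function(records, epsilon = c(0, 0.5, 0.9), quiet = FALSE) {
  req <- c("clade_id", "richness", "stem_age_myr")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("'records' must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (any(epsilon < 0) || any(epsilon >= 1))
    stop("'epsilon' values must be in [0, 1)")
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(records$richness)] <- "missing richness"
  reason[!is.na(records$richness) & records$richness < 1] <- "richness < 1"
  reason[is.na(records$stem_age_myr)] <- "missing stem age"
  reason[!is.na(records$stem_age_myr) & records$stem_age_myr <= 0] <-
    "non-positive stem age"
  keep <- is.na(reason)
  excluded <- data.frame(clade_id = records$clade_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(excluded) && !quiet)
    message("rate_table: excluded ", nrow(excluded), " clade(s): ",
            paste(excluded$clade_id, "(", excluded$reason, ")", collapse = "; "))
  rec <- records[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(epsilon, function(e) {
    data.frame(clade_id = as.character(rec$clade_id),
               richness = rec$richness,
               stem_age_myr = rec$stem_age_myr,
               epsilon = e,
               rate = mom_stem_rate(rec$richness, rec$stem_age_myr, e),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
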