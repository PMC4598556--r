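#' Read a clade trait table
#'
#' Delimited text with one row per terminal clade. Required columns:
#' `clade_id`, `richness`, `stem_age_myr`, `herbivory_prop`; optional:
#' `wings`, `holometaboly` (0/1) and `diet_known` (logical; defaults to
#' `TRUE`). Ranges are validated (`richness >= 1`, `herbivory_prop` in
#' \[0, 1\]) for rows flagged diet-known.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data frame of clade records.
#' @export
read_clade_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = TRUE)
  req <- c("clade_id", "richness", "stem_age_myr", "herbivory_prop")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("clade table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"diet_known" %in% names(d)) d$diet_known <- TRUE
  d$diet_known <- as.logical(d$diet_known)
  known <- which(d$diet_known)
  bad <- known[!is.na(d$herbivory_prop[known]) &
                 (d$herbivory_prop[known] < 0 | d$herbivory_prop[known] > 1)]
  if (length(bad))
    stop("herbivory_prop outside [0, 1] for: ",
         paste(d$clade_id[bad], collapse = ", "))
  if (any(!is.na(d$richness) & d$richness < 1))
    stop("richness < 1 for: ",
         paste(d$clade_id[!is.na(d$richness) & d$richness < 1],
               collapse = ", "))
  d
}

#' Richness-weighted herbivory proportion of a composite clade
#'
#' Aggregates family- or subfamily-level herbivory fractions up to a larger
#' clade as the richness-weighted mean.
#'
#' @param richness species richness of each subunit (>= 0).
#' @param herb_fraction herbivorous fraction of each subunit, in \[0, 1\].
#' @return the aggregate proportion.
#' @examples
#' aggregate_herbivory(c(100, 300), c(1, 0))  # 0.25
#' @export
aggregate_herbivory <- function(richness, herb_fraction) {
  if (length(richness) != length(herb_fraction))
    stop("'richness' and 'herb_fraction' must have equal length")
  if (any(richness < 0)) stop("'richness' must be >= 0")
  if (any(herb_fraction < 0 | herb_fraction > 1))
    stop("'herb_fraction' must be in [0, 1]")
  tot <- sum(richness)
  if (tot == 0) stop("total richness is 0; proportion undefined")
  sum(richness * herb_fraction) / tot
}

#' Herbivorous fraction from a list of feeding types
#'
#' When a clade is recorded with several feeding types but no proportions,
#' the types are assumed equally frequent: the herbivorous fraction is the
#' share of entries equal to `"herbivory"`. Xylophagy (and every other
#' label) is distinct from herbivory — only feeding on living vascular
#' plant tissue counts.
#'
#' @param feeding_types non-empty character vector of feeding-type labels.
#' @return fraction in \[0, 1\].
#' @examples
#' code_mixed_diet(c("herbivory", "predation"))               # 0.5
#' code_mixed_diet(c("herbivory", "xylophagy", "fungivory"))  # 1/3
#' @export
code_mixed_diet <- function(feeding_types) {
  if (!is.character(feeding_types) || length(feeding_types) == 0L)
    stop("'feeding_types' must be a non-empty character vector")
  mean(feeding_types == "herbivory")
}

#' Merge terminal clades into larger units
#'
#' Collapses groups of records (for example, non-monophyletic subfamilies
#' back into their family) into single terminal units: richness is summed,
#' herbivory proportions are richness-weighted, binary traits are
#' OR-combined, and the merged unit takes the stem age supplied in the
#' merge map (members of a multi-record group do not share one stem age of
#' their own). Records absent from the map pass through unchanged.
#'
#' @param records clade trait data frame (see [read_clade_table()]).
#' @param merge_map data frame with columns `clade_id`, `merged_id` and
#'   `stem_age_myr` (the merged unit's stem age; may be `NA` for
#'   single-member groups, which keep their own age).
#' @return merged data frame of clade records.
#' @export
merge_clades <- function(records, merge_map) {
  stopifnot(is.data.frame(records), is.data.frame(merge_map),
            all(c("clade_id", "merged_id", "stem_age_myr") %in%
                  names(merge_map)))
  unknown <- setdiff(merge_map$clade_id, records$clade_id)
  if (length(unknown))
    stop("merge_map references unknown clade(s): ",
         paste(unknown, collapse = ", "))
  untouched <- records[!records$clade_id %in% merge_map$clade_id, ,
                       drop = FALSE]
  groups <- split(merge_map, merge_map$merged_id)
  merged <- do.call(rbind, lapply(names(groups), function(gid) {
    g <- groups[[gid]]
    rows <- records[match(g$clade_id, records$clade_id), , drop = FALSE]
    stem <- unique(g$stem_age_myr[!is.na(g$stem_age_myr)])
    if (length(stem) > 1L)
      stop("conflicting stem ages supplied for merged unit ", gid)
    if (length(stem) == 0L) {
      if (nrow(rows) > 1L)
        stop("missing stem age for merged unit ", gid)
      stem <- rows$stem_age_myr
    }
    out <- rows[1L, , drop = FALSE]
    out$clade_id <- gid
    out$richness <- sum(rows$richness)
    out$stem_age_myr <- stem
    out$herbivory_prop <- aggregate_herbivory(rows$richness,
                                              rows$herbivory_prop)
    if ("wings" %in% names(rows)) out$wings <- as.integer(any(rows$wings == 1))
    if ("holometaboly" %in% names(rows))
      out$holometaboly <- as.integer(any(rows$holometaboly == 1))
    if ("diet_known" %in% names(rows)) out$diet_known <- all(rows$diet_known)
    out
  }))
  out <- rbind(untouched, merged)
  rownames(out) <- NULL
  out
}

#' Run the PGLS model battery across trees and extinction fractions
#'
#' The end-to-end comparative analysis: for each tree, each relative
#' extinction fraction and each model formula, estimate clade net
#' diversification rates by [mom_stem_rate()], fit the PGLS regression with
#' ML Pagel's lambda (or a fixed value) and collect one report row per
#' model (r^2, lambda, model P, AIC, delta AIC within each
#' tree x epsilon x response block). Clades flagged `diet_known = FALSE`
#' are excluded (logged) and dropped from the tree; a clade/tip mismatch is
#' an error listing the symmetric difference.
#'
#' @param trees a `phylo` or named list of `phylo`; tips must be clade ids.
#' @param traits clade trait data frame (see [read_clade_table()]).
#' @param epsilon relative extinction fractions (default `c(0, 0.5, 0.9)`).
#' @param formulas character vector of model right-hand sides, e.g.
#'   `c("herbivory_prop", "herbivory_prop + wings")`.
#' @param response `"rate"` (net diversification) or `"log_richness"`
#'   (natural-log species richness; epsilon is then irrelevant and only the
#'   first value is used).
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @param richness_rate also fit log_richness ~ rate per tree x epsilon
#'   (the rate/richness coupling check).
#' @param quiet suppress progress messages.
#' @return object of class `order_analysis`: list with `models` (report
#'   data frame) and `fits` (named list of `pgls_fit`).
#' @export
run_order_analysis <- function(trees, traits,
                               epsilon = c(0, 0.5, 0.9),
                               formulas = "herbivory_prop",
                               response = c("rate", "log_richness"),
                               lambda = "ML",
                               richness_rate = FALSE,
                               quiet = FALSE) {
  response <- match.arg(response)
  if (inherits(trees, "phylo")) trees <- list(tree = trees)
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  n_unknown <- sum(!traits$diet_known)
  if (n_unknown > 0) {
    if (!quiet)
      message("run_order_analysis: excluding ", n_unknown,
              " clade(s) with unknown diet: ",
              paste(traits$clade_id[!traits$diet_known], collapse = ", "))
    traits <- traits[traits$diet_known, , drop = FALSE]
  }
  if (response == "log_richness") epsilon <- epsilon[1L]
  rows <- list()
  fits <- list()
  for (tn in names(trees)) {
    tree <- trees[[tn]]
    mism <- c(setdiff(tree$tip.label, traits$clade_id),
              setdiff(traits$clade_id, tree$tip.label))
    extra_tips <- setdiff(tree$tip.label, traits$clade_id)
    if (length(extra_tips) == length(mism) && length(extra_tips) > 0) {
      # tips without trait rows are the excluded clades; drop them
      tree <- ape::drop.tip(tree, extra_tips)
    } else if (length(mism)) {
      stop("clade/tip mismatch for tree '", tn, "': ",
           paste(unique(mism), collapse = ", "))
    }
    for (eps in epsilon) {
      d <- traits[match(tree$tip.label, traits$clade_id), , drop = FALSE]
      d$rate <- mom_stem_rate(d$richness, d$stem_age_myr, eps)
      d$log_richness <- log(d$richness)
      resp_col <- if (response == "rate") "rate" else "log_richness"
      fml_set <- formulas
      if (richness_rate) fml_set <- c(fml_set, ".rate_coupling")
      for (fml in fml_set) {
        if (fml == ".rate_coupling") {
          this_resp <- "log_richness"; rhs <- "rate"
        } else {
          this_resp <- resp_col; rhs <- fml
        }
        fit <- pgls(stats::reformulate(rhs, response = this_resp), d, tree,
                    lambda = lambda)
        key <- sprintf("%s | eps=%g | %s ~ %s", tn, eps, this_resp, rhs)
        fits[[key]] <- fit
        herb_row <- match("herbivory_prop", fit$coefficients$term)
        rows[[length(rows) + 1L]] <- data.frame(
          tree = tn, epsilon = eps, response = this_resp, model = rhs,
          n = fit$n, lambda = fit$lambda,
          r_squared = fit$r_squared, model_p = fit$model_p,
          herb_p = if (is.na(herb_row)) NA_real_
                   else fit$coefficients$p[herb_row],
          herb_coef = if (is.na(herb_row)) NA_real_
                      else fit$coefficients$estimate[herb_row],
          logLik = fit$logLik, aic = fit$aic,
          stringsAsFactors = FALSE)
      }
    }
  }
  models <- do.call(rbind, rows)
  grp <- interaction(models$tree, models$epsilon, models$response, drop = TRUE)
  models$delta_aic <- models$aic -
    stats::ave(models$aic, grp, FUN = min)
  structure(list(models = models, fits = fits), class = "order_analysis")
}

#' @export
print.order_analysis <- function(x, digits = 4, ...) {
  cat("PGLS model battery:", nrow(x$models), "fits\n")
  m <- x$models
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], signif, digits = digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Run the sister-clade comparison analysis
#'
#' Extracts non-overlapping least-inclusive sister pairs differing in the
#' presence of herbivory and summarizes them with the exact one-tailed sign
#' test. When no informative pair exists the report says so instead of
#' erroring.
#'
#' @param tree rooted binary `phylo` whose tips are the analysis units.
#' @param traits clade trait data frame with `clade_id`, `herbivory_prop`
#'   and `richness` covering the tree's tips.
#' @param threshold herbivory-presence threshold (see
#'   [extract_sister_pairs()]).
#' @param quiet suppress messages.
#' @return object of class `sister_analysis`: list with `pairs` (data
#'   frame) and `summary` (a `sign_test_result`, or `NULL` when there are
#'   no informative pairs).
#' @export
run_sister_analysis <- function(tree, traits, threshold = 0, quiet = FALSE) {
  herb <- stats::setNames(traits$herbivory_prop, traits$clade_id)
  rich <- stats::setNames(traits$richness, traits$clade_id)
  pairs <- extract_sister_pairs(tree, herb, rich, threshold = threshold)
  summary <- NULL
  if (nrow(pairs) == 0L) {
    if (!quiet) message("run_sister_analysis: no informative sister pairs")
  } else {
    summary <- pair_summary(pairs, quiet = quiet)
  }
  structure(list(pairs = pairs, summary = summary),
            class = "sister_analysis")
}

#' Pool sister-clade analyses across scopes
#'
#' Concatenates the pair tables of several [run_sister_analysis()] results
#' (for example, one per order plus the among-order pairs) and re-runs the
#' sign test on the union.
#'
#' @param results list of `sister_analysis` objects.
#' @return a `sister_analysis` over the pooled pairs.
#' @export
pool_sister_results <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "sister_analysis")))
  pairs <- do.call(rbind, lapply(results, function(r)
    r$pairs[, setdiff(names(r$pairs), "node"), drop = FALSE]))
  summary <- if (nrow(pairs)) pair_summary(pairs, quiet = TRUE) else NULL
  structure(list(pairs = pairs, summary = summary),
            class = "sister_analysis")
}

#' @export
print.sister_analysis <- function(x, ...) {
  cat("Sister-clade comparison:", nrow(x$pairs), "pair(s)\n")
  if (is.null(x$summary)) cat("No informative pairs.\n")
  else print(x$summary)
  invisible(x)
}
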