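#' Exact one-tailed paired sign test
#'
#' Upper-tail binomial probability of observing at least `k` successes out
#' of `n` informative pairs under a fair coin:
#' P = sum_{i=k}^{n} choose(n, i) / 2^n.
#'
#' @param k number of successes (pairs where the herbivory-bearing clade is
#'   strictly richer), 0 <= k <= n.
#' @param n number of informative (non-tied) pairs, >= 1.
#' @return one-tailed P value in (0, 1].
#' @examples
#' sign_test(5, 5)    # 0.03125
#' sign_test(13, 21)  # 0.191655
#' @export
sign_test <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || anyNA(c(k, n)) ||
      k != round(k) || n != round(n))
    stop("'k' and 'n' must be single integers")
  if (n < 1) stop("no informative pairs (n must be >= 1)")
  if (k < 0 || k > n) stop("'k' must satisfy 0 <= k <= n")
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Extract non-overlapping least-inclusive sister-clade pairs
#'
#' Walks the tree and reports sister pairs (the two children of one node)
#' in which herbivory is present in one child clade — any tip with
#' herbivory proportion above `threshold`, regardless of how small — and
#' absent from every tip of the other. Pairs are selected greedily from the
#' least inclusive candidates outward (smallest combined tip count, ties
#' broken by lexicographic clade label), and a clade used in one pair is
#' never reused, so reported pairs are mutually non-overlapping and no
#' reported clade is nested inside another. Both members of a pair share
#' the stem age of their parent node by construction.
#'
#' @param tree rooted binary `phylo` whose tips are the analysis units.
#' @param herb named numeric vector of herbivory proportions (or logical
#'   presence) covering every tip.
#' @param richness named numeric vector of species richness per tip.
#' @param threshold herbivory proportion strictly above which herbivory is
#'   scored present (default 0: present "regardless of proportion").
#' @return data frame with one row per pair: `node`, `clade_herb`,
#'   `clade_nonherb` (sorted member tips joined by `+`), `n_tips_herb`,
#'   `n_tips_nonherb`, `richness_herb`, `richness_nonherb`, `stem_age`.
#'   The member tip sets are attached as attribute `"tip_sets"`.
#' @export
extract_sister_pairs <- function(tree, herb, richness, threshold = 0) {
  validate_timetree(tree)
  if (!ape::is.binary(tree))
    stop("tree contains polytomies; sister pairs are not well defined")
  miss <- setdiff(tree$tip.label, names(herb))
  if (length(miss))
    stop("tips missing a herbivory state: ", paste(miss, collapse = ", "))
  missr <- setdiff(tree$tip.label, names(richness))
  if (length(missr))
    stop("tips missing richness: ", paste(missr, collapse = ", "))
  present <- if (is.logical(herb)) herb else herb > threshold
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)

  # tip sets per node by postorder accumulation
  tipsets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- tree$tip.label[i]
  edg <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(edg)))
    tipsets[[edg[r, 1L]]] <- c(tipsets[[edg[r, 1L]]], tipsets[[edg[r, 2L]]])

  clade_label <- function(tips) paste(sort(tips), collapse = "+")
  internal <- ntip + seq_len(tree$Nnode)
  cands <- list()
  for (nd in internal) {
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    if (length(kids) != 2L) next
    t1 <- tipsets[[kids[1L]]]; t2 <- tipsets[[kids[2L]]]
    a1 <- any(present[t1]); a2 <- any(present[t2])
    if (xor(a1, a2)) {
      hb <- if (a1) t1 else t2
      nh <- if (a1) t2 else t1
      cands[[length(cands) + 1L]] <- list(
        node = nd, herb_tips = hb, nonherb_tips = nh,
        size = length(t1) + length(t2),
        label = min(clade_label(hb), clade_label(nh)),
        stem_age = ages[nd])
    }
  }
  chosen <- list()
  used <- character(0)
  while (length(cands)) {
    sizes <- vapply(cands, `[[`, numeric(1), "size")
    labs <- vapply(cands, `[[`, character(1), "label")
    ord <- order(sizes, labs)
    pick <- cands[[ord[1L]]]
    chosen[[length(chosen) + 1L]] <- pick
    used <- c(used, pick$herb_tips, pick$nonherb_tips)
    cands <- Filter(function(cd)
      !any(c(cd$herb_tips, cd$nonherb_tips) %in% used), cands)
  }
  if (!length(chosen)) {
    out <- data.frame(node = integer(0), clade_herb = character(0),
                      clade_nonherb = character(0),
                      n_tips_herb = integer(0), n_tips_nonherb = integer(0),
                      richness_herb = numeric(0),
                      richness_nonherb = numeric(0),
                      stem_age = numeric(0), stringsAsFactors = FALSE)
    attr(out, "tip_sets") <- list()
    return(out)
  }
  out <- data.frame(
    node = vapply(chosen, `[[`, numeric(1), "node"),
    clade_herb = vapply(chosen, function(p) clade_label(p$herb_tips),
                        character(1)),
    clade_nonherb = vapply(chosen, function(p) clade_label(p$nonherb_tips),
                           character(1)),
    n_tips_herb = vapply(chosen, function(p) length(p$herb_tips), integer(1)),
    n_tips_nonherb = vapply(chosen, function(p) length(p$nonherb_tips),
                            integer(1)),
    richness_herb = vapply(chosen, function(p) sum(richness[p$herb_tips]),
                           numeric(1)),
    richness_nonherb = vapply(chosen,
                              function(p) sum(richness[p$nonherb_tips]),
                              numeric(1)),
    stem_age = vapply(chosen, `[[`, numeric(1), "stem_age"),
    stringsAsFactors = FALSE
  )
  attr(out, "tip_sets") <- lapply(chosen, function(p)
    list(herb = p$herb_tips, nonherb = p$nonherb_tips))
  out
}

#' Summarize sister pairs with an exact sign test
#'
#' Counts the pairs in which the herbivory-bearing clade is strictly richer
#' than its non-herbivorous sister, drops richness ties from the sample
#' (logged), and computes the exact one-tailed sign-test P value.
#'
#' @param pairs data frame from [extract_sister_pairs()] (or any data frame
#'   with `richness_herb` and `richness_nonherb` columns).
#' @param quiet suppress the tie-exclusion message.
#' @return an object of class `sign_test_result`: list with `n_pairs`
#'   (total), `ties`, `n` (informative pairs), `k` (successes) and
#'   `p_one_tailed`.
#' @export
pair_summary <- function(pairs, quiet = FALSE) {
  stopifnot(is.data.frame(pairs),
            all(c("richness_herb", "richness_nonherb") %in% names(pairs)))
  if (nrow(pairs) < 1L) stop("need at least one sister pair")
  wins <- pairs$richness_herb > pairs$richness_nonherb
  ties <- pairs$richness_herb == pairs$richness_nonherb
  n_inf <- sum(!ties)
  if (sum(ties) && !quiet)
    message("pair_summary: excluded ", sum(ties), " richness tie(s)")
  if (n_inf == 0L) stop("no informative pairs: all richness values tied")
  k <- sum(wins)
  structure(list(n_pairs = nrow(pairs), ties = sum(ties), n = n_inf, k = k,
                 p_one_tailed = sign_test(k, n_inf)),
            class = "sign_test_result")
}

#' @export
print.sign_test_result <- function(x, ...) {
  cat(sprintf(
    "Sign test: %d pairs (%d tie%s excluded), herbivorous clade richer in %d of %d; one-tailed P = %.6g\n",
    x$n_pairs, x$ties, if (x$ties == 1) "" else "s", x$k, x$n, x$p_one_tailed))
  invisible(x)
}
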