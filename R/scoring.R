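# The match-point system: score each POP against a compound's PEC set
# (1 = correct, 0.5 = partially correct, 0 = incorrect) and aggregate per
# cluster.

map_pair <- function(keys, pk_table) {
  vapply(strsplit(keys, ".", fixed = TRUE), function(toks) {
    canonical_pair(pk_classify(toks[1], pk_table), pk_classify(toks[2], pk_table))
  }, character(1))
}

#' Score one POP against a PEC set
#'
#' Both sides are first mapped onto the polyketide comparison class
#' (symmetric mapping, so a predicted `ohmal` and a backbone `pk` unit
#' collapse to the same token), then:
#' \enumerate{
#'   \item the mapped POP equals some mapped PEC: a correct match, 1 point;
#'   \item exactly one POP token is the unresolved `nrp` and the other
#'     token occurs in at least one mapped PEC: a partially correct match
#'     (one out-of-consensus subunit), 0.5 points;
#'   \item otherwise (including `nrp.nrp` and pairs whose tokens exist in
#'     the compound but never adjacently): incorrect, 0 points.
#' }
#' PECs are not consumed: one PEC may match several POPs.
#'
#' @param pop Canonical POP key, e.g. `"orn.ser"`.
#' @param pecs Character vector of PEC keys (the support of a compound's
#'   fragment multiset; PECs contain no `nrp` tokens).
#' @param pk_table Polyketide class table.
#' @return List of class `match_result`: `pop`, `points` (1, 0.5 or 0),
#'   `match_kind` (`"exact"`, `"partial_nrp"`, `"none"`), `matched_pec`
#'   (first matching PEC, or `NA`).
#' @examples
#' pecs <- unique_pairs(pecs_for(default_compound_library()[["Delftibactin"]]))
#' match_pop("orn.ser", pecs)$points   # 1
#' match_pop("nrp.pk", pecs)$points    # 0.5
#' match_pop("ohmal.ser", pecs)$points # 0
#' @export
match_pop <- function(pop, pecs, pk_table = default_pk_class()) {
  stopifnot(length(pop) == 1L)
  if (inherits(pecs, "pair_multiset")) pecs <- unique_pairs(pecs)
  mapped_pop <- map_pair(pop, pk_table)
  mapped_pecs <- map_pair(pecs, pk_table)
  pop_toks <- strsplit(mapped_pop, ".", fixed = TRUE)[[1]]
  hit <- match(mapped_pop, mapped_pecs)
  if (!is.na(hit)) {
    res <- list(pop = pop, points = 1, match_kind = "exact",
                matched_pec = pecs[hit])
  } else if (sum(pop_toks == "nrp") == 1L &&
             pop_toks[pop_toks != "nrp"] %in%
               unlist(strsplit(mapped_pecs, ".", fixed = TRUE))) {
    res <- list(pop = pop, points = 0.5, match_kind = "partial_nrp",
                matched_pec = NA_character_)
  } else {
    res <- list(pop = pop, points = 0, match_kind = "none",
                matched_pec = NA_character_)
  }
  structure(res, class = "match_result")
}

#' Score a set of POP keys against a PEC set
#'
#' Vectorized convenience over [match_pop()].
#'
#' @param pops Character vector of POP keys.
#' @param pecs PEC keys (or a [pair_multiset()]).
#' @param pk_table Polyketide class table.
#' @return `data.frame` with columns `pop`, `points`, `match_kind`,
#'   `matched_pec`.
#' @export
score_pairs <- function(pops, pecs, pk_table = default_pk_class()) {
  res <- lapply(pops, match_pop, pecs = pecs, pk_table = pk_table)
  data.frame(pop = vapply(res, `[[`, character(1), "pop"),
             points = vapply(res, `[[`, numeric(1), "points"),
             match_kind = vapply(res, `[[`, character(1), "match_kind"),
             matched_pec = vapply(res, `[[`, character(1), "matched_pec"),
             stringsAsFactors = FALSE)
}

#' Score a cluster's POPs against a known compound
#'
#' Derives the record's POPs, scores each against the compound's PECs and
#' sums the points. By default each distinct POP is scored once (pairs are
#' types, not slots); `with_multiplicity = TRUE` scores every occurrence,
#' for sensitivity analysis. The per-cluster fraction of correct points is
#' `total_points / n_pops`.
#'
#' @param r A [cluster_record()].
#' @param compound A `compound_entry`.
#' @param policy Consensus policy.
#' @param pk_table Polyketide class table.
#' @param n_gram_size Fragment size.
#' @param with_multiplicity Score POP occurrences instead of distinct POPs.
#' @return Object of class `cluster_score`: `cluster_key`, `compound`,
#'   `results` (the [score_pairs()] table), `total_points`, `n_pops`,
#'   `fraction_correct`, `identity_percent` (from the record's
#'   `known_match`, else `NA`), `no_pops` flag.
#' @export
score_cluster <- function(r, compound, policy = "strict",
                          pk_table = default_pk_class(), n_gram_size = 2,
                          with_multiplicity = FALSE) {
  ms <- pops_for(r, policy = policy, n_gram_size = n_gram_size)
  pecs <- unique_pairs(pecs_for(compound, n_gram_size = n_gram_size))
  pops <- if (with_multiplicity) rep(names(ms), ms) else unique_pairs(ms)
  results <- score_pairs(pops, pecs, pk_table = pk_table)
  n_pops <- nrow(results)
  total <- sum(results$points)
  structure(list(cluster_key = cluster_key(r),
                 compound = compound$name,
                 results = results,
                 total_points = total,
                 n_pops = n_pops,
                 fraction_correct = if (n_pops > 0L) total / n_pops else 0,
                 identity_percent = if (is.null(r$known_match)) NA_real_ else
                   r$known_match$identity_percent,
                 no_pops = n_pops == 0L),
            class = "cluster_score")
}

#' @export
print.cluster_score <- function(x, ...) {
  cat(sprintf("<cluster score> %s vs %s: %.1f / %d points (fraction %.3f)\n",
              x$cluster_key, x$compound, x$total_points, x$n_pops,
              x$fraction_correct))
  invisible(x)
}

#' Pair genomic identity with prediction correctness
#'
#' Builds the per-cluster table relating the percent of genes homologous to
#' the most similar known cluster with the fraction of correct POPs, and
#' summarizes it with a Spearman rank correlation. Clusters lacking an
#' identity annotation are flagged `excluded` and dropped from the
#' correlation; the correlation is flagged undefined when fewer than two
#' usable rows remain or either column has zero variance.
#'
#' @param scores List of [score_cluster()] results.
#' @return `data.frame` with columns `cluster_key`, `identity_percent`,
#'   `fraction_correct`, `excluded`; attributes `spearman_rho` (numeric or
#'   `NA`) and `correlation_defined` (logical).
#' @export
identity_vs_correctness <- function(scores) {
  if (inherits(scores, "cluster_score")) scores <- list(scores)
  tab <- data.frame(
    cluster_key = vapply(scores, `[[`, character(1), "cluster_key"),
    identity_percent = vapply(scores, `[[`, numeric(1), "identity_percent"),
    fraction_correct = vapply(scores, `[[`, numeric(1), "fraction_correct"),
    stringsAsFactors = FALSE
  )
  tab$excluded <- is.na(tab$identity_percent)
  use <- tab[!tab$excluded, ]
  defined <- nrow(use) >= 2L &&
    stats::sd(use$identity_percent) > 0 && stats::sd(use$fraction_correct) > 0
  rho <- if (defined) {
    stats::cor(use$identity_percent, use$fraction_correct, method = "spearman")
  } else NA_real_
  attr(tab, "spearman_rho") <- rho
  attr(tab, "correlation_defined") <- defined
  tab
}

#' Write a score report as TSV
#'
#' One row per scored POP (`cluster_key`, `compound`, `pop`, `points`,
#' `match_kind`, `identity_percent`) plus a per-cluster summary TSV when
#' `summary_path` is given.
#'
#' @param scores List of `cluster_score` objects.
#' @param path Detail report path.
#' @param summary_path Optional per-cluster summary path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(scores, path, summary_path = NULL) {
  if (inherits(scores, "cluster_score")) scores <- list(scores)
  detail <- do.call(rbind, lapply(scores, function(s) {
    if (!nrow(s$results)) return(NULL)
    cbind(data.frame(cluster_key = s$cluster_key, compound = s$compound,
                     stringsAsFactors = FALSE),
          s$results[c("pop", "points", "match_kind")],
          data.frame(identity_percent = s$identity_percent))
  }))
  if (is.null(detail)) {
    detail <- data.frame(cluster_key = character(0), compound = character(0),
                         pop = character(0), points = numeric(0),
                         match_kind = character(0),
                         identity_percent = numeric(0))
  }
  utils::write.table(detail, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    summ <- data.frame(
      cluster_key = vapply(scores, `[[`, character(1), "cluster_key"),
      compound = vapply(scores, `[[`, character(1), "compound"),
      total_points = vapply(scores, `[[`, numeric(1), "total_points"),
      n_pops = vapply(scores, `[[`, integer(1), "n_pops"),
      fraction_correct = vapply(scores, `[[`, numeric(1), "fraction_correct"),
      identity_percent = vapply(scores, `[[`, numeric(1), "identity_percent"),
      stringsAsFactors = FALSE
    )
    utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
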