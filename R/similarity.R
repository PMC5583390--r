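# Binary POP matrices, Jaccard-index similarity, hierarchical clustering,
# and POP distribution tables (global, per cohort, per dendrogram branch).

#' Binary presence/absence matrix of POPs
#'
#' Instances (rows) are gene clusters or organisms; attributes (columns)
#' are all observed pairs in alphabetical order; a cell is 1 iff the
#' instance's POP set contains the pair. At organism granularity an
#' organism's row is the union of its clusters' POP sets. Ordering is
#' deterministic: rows follow record order (organisms by first
#' appearance), columns are sorted.
#'
#' @param rs A [record_set()].
#' @param granularity `"cluster"` (default; rows keyed like
#'   `"B. caribensis-C9"`) or `"organism"`.
#' @param policy Consensus policy.
#' @param n_gram_size Fragment size.
#' @return Integer 0/1 matrix with dimnames; attribute `empty_instances`
#'   names rows with no POPs (all-zero rows). An empty record set gives a
#'   0 x 0 matrix.
#' @export
build_binary_matrix <- function(rs, granularity = c("cluster", "organism"),
                                policy = "strict", n_gram_size = 2) {
  granularity <- match.arg(granularity)
  if (!length(rs$records)) {
    return(matrix(integer(0), 0, 0))
  }
  supports <- lapply(rs$records, function(r) {
    unique_pairs(pops_for(r, policy = policy, n_gram_size = n_gram_size))
  })
  ids <- vapply(rs$records, cluster_key, character(1))
  if (granularity == "organism") {
    orgs <- vapply(rs$records, `[[`, character(1), "organism")
    supports <- lapply(split(supports, factor(orgs, levels = unique(orgs))),
                       function(s) unique(unlist(s)))
    ids <- unique(orgs)
  }
  attrs <- sort(unique(unlist(supports)))
  m <- matrix(0L, nrow = length(ids), ncol = length(attrs),
              dimnames = list(ids, attrs))
  for (i in seq_along(supports)) {
    m[i, supports[[i]]] <- 1L
  }
  attr(m, "empty_instances") <- ids[lengths(supports) == 0L]
  m
}

#' Jaccard index of two pair sets
#'
#' `|A intersect B| / |A union B|`, in \[0, 1\]: 1 for equal nonempty sets,
#' 0 for disjoint sets. Defined as 0 when both sets are empty, with
#' attribute `both_empty = TRUE` flagging the degenerate case.
#'
#' @param a,b Character vectors of pair keys (or [pair_multiset()]s, whose
#'   supports are used).
#' @return Single number in \[0, 1\].
#' @examples
#' jaccard_index(c("asp.nrp", "asp.ser", "orn.ser"),
#'               c("asp.nrp", "asp.ser", "orn.ser"))  # 1
#' @export
jaccard_index <- function(a, b) {
  if (inherits(a, "pair_multiset")) a <- unique_pairs(a)
  if (inherits(b, "pair_multiset")) b <- unique_pairs(b)
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    return(structure(0, both_empty = TRUE))
  }
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard-index matrix
#'
#' Applies [jaccard_index()] to every pair of rows of a binary matrix
#' (using the row supports). Symmetric, unit diagonal for nonempty rows.
#'
#' @param m Binary matrix from [build_binary_matrix()].
#' @return Numeric matrix with the instance ids as dimnames.
#' @export
jaccard_matrix <- function(m) {
  if (!nrow(m)) stop("empty binary matrix", call. = FALSE)
  n <- nrow(m)
  ids <- rownames(m)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  supports <- lapply(seq_len(n), function(i) colnames(m)[m[i, ] == 1L])
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- as.numeric(jaccard_index(supports[[i]], supports[[j]]))
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Hierarchical clustering of the binary matrix
#'
#' Agglomerative clustering of instances over their 0/1 POP vectors,
#' Euclidean distance, average linkage — the standard heatmap-sidebar
#' clustering. Deterministic for a fixed input ordering. Optionally also
#' clusters the attribute axis.
#'
#' @param m Binary matrix with at least 2 rows.
#' @param cluster_columns Also return a column dendrogram.
#' @return List of class `rinpep_dendrogram`: `hclust` (a
#'   [stats::hclust()] tree), `leaf_order` (instance ids in dendrogram
#'   order), and `hclust_columns` when requested.
#' @export
hierarchical_cluster <- function(m, cluster_columns = FALSE) {
  if (nrow(m) < 2L) stop("need at least 2 instances to cluster", call. = FALSE)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  res <- list(hclust = hc, leaf_order = rownames(m)[hc$order])
  if (cluster_columns && ncol(m) >= 2L) {
    hcc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                         method = "average")
    res$hclust_columns <- hcc
  }
  structure(res, class = "rinpep_dendrogram")
}

#' Serialize a dendrogram as Newick
#'
#' @param d A `rinpep_dendrogram` (or plain `hclust`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(d, path) {
  hc <- if (inherits(d, "rinpep_dendrogram")) d$hclust else d
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' POP distribution table
#'
#' Counts every pair across a group of fragment multisets and reports its
#' percentage of the total. With multiplicity (the default) a pair
#' occurring twice in one backbone counts twice; the unique-pair view
#' counts each multiset's support once.
#'
#' @param group A [pair_multiset()] or list of them.
#' @param with_multiplicity Use multiplicities (default) or supports.
#' @return `data.frame` (`pair`, `count`, `percent`) sorted by descending
#'   count then pair key; percents sum to 100.
#' @export
pop_distribution <- function(group, with_multiplicity = TRUE) {
  if (inherits(group, "pair_multiset")) group <- list(group)
  if (!length(group)) stop("empty group", call. = FALSE)
  counts <- list()
  for (ms in group) {
    n <- if (with_multiplicity) as.integer(ms) else rep(1L, length(ms))
    for (k in seq_along(ms)) {
      key <- names(ms)[k]
      counts[[key]] <- (counts[[key]] %||% 0L) + n[k]
    }
  }
  if (!length(counts)) {
    stop("group contains no fragments", call. = FALSE)
  }
  tab <- data.frame(pair = names(counts), count = unlist(counts, use.names = FALSE),
                    stringsAsFactors = FALSE)
  tab$percent <- 100 * tab$count / sum(tab$count)
  tab <- tab[order(-tab$count, tab$pair), ]
  rownames(tab) <- NULL
  tab
}

#' Side-by-side PEC vs POP distribution
#'
#' For every record whose most-similar-known-compound resolves in the
#' library, accumulates the compound's PEC multiset and the record's POP
#' multiset, then reports both distributions over the union pair
#' vocabulary — the ideal prediction makes the two columns identical.
#' Records without a resolvable known match are flagged in attribute
#' `excluded` and skipped.
#'
#' @param rs A [record_set()].
#' @param library A `compound_library`.
#' @param policy,n_gram_size,with_multiplicity Passed through.
#' @return `data.frame` (`pair`, `percent_pec`, `percent_pop`), sorted by
#'   pair key; each percent column sums to 100.
#' @export
pec_vs_pop_distribution <- function(rs, library, policy = "strict",
                                    n_gram_size = 2, with_multiplicity = TRUE) {
  pec_ms <- list(); pop_ms <- list(); excluded <- character(0)
  for (r in rs$records) {
    nm <- if (is.null(r$known_match)) NA_character_ else r$known_match$compound_name
    if (is.na(nm) || !nm %in% names(library)) {
      excluded <- c(excluded, cluster_key(r))
      next
    }
    pec_ms[[length(pec_ms) + 1L]] <-
      pecs_for(library[[nm]], n_gram_size = n_gram_size)
    pop_ms[[length(pop_ms) + 1L]] <-
      pops_for(r, policy = policy, n_gram_size = n_gram_size)
  }
  if (!length(pec_ms)) stop("no records resolve in the compound library", call. = FALSE)
  dpec <- pop_distribution(pec_ms, with_multiplicity = with_multiplicity)
  dpop <- pop_distribution(pop_ms, with_multiplicity = with_multiplicity)
  pairs <- sort(union(dpec$pair, dpop$pair))
  tab <- data.frame(
    pair = pairs,
    percent_pec = dpec$percent[match(pairs, dpec$pair)],
    percent_pop = dpop$percent[match(pairs, dpop$pair)],
    stringsAsFactors = FALSE
  )
  tab$percent_pec[is.na(tab$percent_pec)] <- 0
  tab$percent_pop[is.na(tab$percent_pop)] <- 0
  attr(tab, "excluded") <- excluded
  tab
}

#' Read a branch assignment table
#'
#' Two-column TSV `cluster_key`, `branch` mapping clusters to the main
#' branches of an externally built dendrogram (branch labels like
#' `Branch_1` ... `Branch_6`).
#'
#' @param path TSV path.
#' @return Named character vector, cluster keys to branch labels.
#' @export
read_branch_assignments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("cluster_key", "branch") %in% names(tab))) {
    stop("branch assignment table needs columns 'cluster_key' and 'branch'",
         call. = FALSE)
  }
  stats::setNames(tab$branch, tab$cluster_key)
}

#' Per-branch POP distributions
#'
#' One [pop_distribution()] per dendrogram branch plus a global table
#' under `"Branch_0"` covering every assigned record. Assigned keys that
#' do not exist in the record set are an error; a branch whose clusters
#' contribute no fragments yields an empty table flagged `empty`.
#'
#' @param rs A [record_set()].
#' @param ba Named character vector from [read_branch_assignments()].
#' @param policy,n_gram_size,with_multiplicity Passed through.
#' @return Named list of distribution `data.frame`s, `Branch_0` first.
#' @export
branch_distribution <- function(rs, ba, policy = "strict", n_gram_size = 2,
                                with_multiplicity = TRUE) {
  keys <- vapply(rs$records, cluster_key, character(1))
  missing <- setdiff(names(ba), keys)
  if (length(missing)) {
    stop("branch assignments reference unknown clusters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  assigned <- rs$records[keys %in% names(ba)]
  if (!length(assigned)) stop("no records are assigned to branches", call. = FALSE)
  ms_all <- lapply(assigned, pops_for, policy = policy,
                   n_gram_size = n_gram_size)
  branch_of <- unname(ba[vapply(assigned, cluster_key, character(1))])
  out <- list(Branch_0 = pop_distribution(ms_all,
                                          with_multiplicity = with_multiplicity))
  for (b in unique(branch_of)) {
    ms <- ms_all[branch_of == b]
    out[[b]] <- tryCatch(
      pop_distribution(ms, with_multiplicity = with_multiplicity),
      error = function(e) {
        structure(data.frame(pair = character(0), count = integer(0),
                             percent = numeric(0)), empty = TRUE)
      }
    )
  }
  out
}

#' Write a matrix as a heatmap-tool-compatible TSV
#'
#' Instances x attributes with an `id` first column, suitable as input for
#' heatmap tools (the same layout works for the binary matrix and the
#' Jaccard matrix).
#'
#' @param m Matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  tab <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distribution table as TSV
#'
#' @param tab Distribution `data.frame` (or named list of them, written
#'   with a leading `branch` column).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distribution_tsv <- function(tab, path) {
  if (is.data.frame(tab)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rows <- do.call(rbind, lapply(names(tab), function(b) {
      d <- tab[[b]]
      if (!nrow(d)) return(NULL)
      cbind(data.frame(branch = b, stringsAsFactors = FALSE), d)
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
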