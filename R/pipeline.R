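# End-to-end orchestration: ingest -> POPs -> scoring -> matrices -> JI ->
# clustering -> distributions -> networks, with a reproducible run
# manifest.

#' Run the full analysis pipeline
#'
#' Executes every stage over a cluster-record file and a compound library
#' and writes all artifacts into `out_dir`:
#' \itemize{
#'   \item `pops.tsv` — per-cluster fragment multisets;
#'   \item `scores.tsv`, `score_summary.tsv`,
#'     `identity_vs_correctness.tsv` — the match-point system, for records
#'     whose known compound resolves in the library;
#'   \item `binary_matrix.tsv`, `jaccard_matrix.tsv`,
#'     `dendrogram.newick` — presence/absence fingerprints, Jaccard
#'     similarity, Euclidean average-linkage clustering;
#'   \item `pop_distribution.tsv`, `pec_vs_pop.tsv` — distribution tables;
#'   \item `network.sif`, `network.graphml`, `node_attributes.tsv`;
#'   \item `manifest.json` — inputs, options, seed, package version and an
#'     MD5 checksum per output, sufficient to verify a byte-identical
#'     re-run.
#' }
#' Per-stage record counts (clusters ingested, clusters without POPs,
#' records scored) are logged to standard error so the natural filtering
#' of prediction-less records is auditable. An empty records file aborts
#' before any output is written.
#'
#' @param records_path Cluster record JSON/TSV.
#' @param out_dir Output directory (created if needed).
#' @param library_path Compound library TSV; `NULL` uses the bundled
#'   library.
#' @param policy Consensus policy (`"strict"` or `"majority"`).
#' @param n_gram_size Fragment size (1, 2 or 3).
#' @param granularity Matrix rows: `"cluster"` or `"organism"`.
#' @param network_mode `"compound"` or `"pop"`.
#' @param min_edges Degree threshold for the exported network subset;
#'   0 keeps everything.
#' @param seed Optional integer seed set before the run.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(records_path, out_dir, library_path = NULL,
                         policy = "strict", n_gram_size = 2,
                         granularity = "cluster",
                         network_mode = "compound", min_edges = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  rs <- read_cluster_records(records_path)
  if (!length(rs$records)) {
    stop("no cluster records in ", records_path, call. = FALSE)
  }
  lib <- if (is.null(library_path)) default_compound_library() else
    load_compound_library(library_path)
  message(sprintf("ingest: %d clusters from %s", length(rs$records),
                  records_path))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    outputs <<- c(outputs, path)
    path
  }

  ms_list <- lapply(rs$records, pops_for, policy = policy,
                    n_gram_size = n_gram_size)
  no_pops <- sum(!lengths(ms_list))
  message(sprintf("fragment: %d clusters without POPs (inert)", no_pops))
  write_pair_multisets(ms_list, emit("pops.tsv"))

  scorable <- Filter(function(r) {
    !is.null(r$known_match) && r$known_match$compound_name %in% names(lib)
  }, rs$records)
  if (length(scorable)) {
    scores <- lapply(scorable, function(r) {
      score_cluster(r, lib[[r$known_match$compound_name]], policy = policy,
                    n_gram_size = n_gram_size)
    })
    message(sprintf("score: %d clusters scored against %d library compounds",
                    length(scores), length(lib)))
    write_score_report(scores, emit("scores.tsv"), emit("score_summary.tsv"))
    ivc <- identity_vs_correctness(scores)
    utils::write.table(ivc, emit("identity_vs_correctness.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    message("score: no records resolve in the compound library; skipping")
  }

  bm <- build_binary_matrix(rs, granularity = granularity, policy = policy,
                            n_gram_size = n_gram_size)
  write_matrix_tsv(bm, emit("binary_matrix.tsv"))
  if (nrow(bm) && ncol(bm)) {
    write_matrix_tsv(jaccard_matrix(bm), emit("jaccard_matrix.tsv"))
    if (nrow(bm) >= 2L) {
      write_dendrogram_newick(hierarchical_cluster(bm),
                              emit("dendrogram.newick"))
    }
  }

  nonempty <- Filter(length, ms_list)
  if (length(nonempty)) {
    write_distribution_tsv(pop_distribution(nonempty),
                           emit("pop_distribution.tsv"))
  }
  pvp <- tryCatch(pec_vs_pop_distribution(rs, lib, policy = policy,
                                          n_gram_size = n_gram_size),
                  error = function(e) NULL)
  if (!is.null(pvp)) {
    utils::write.table(pvp, emit("pec_vs_pop.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  net <- build_network(rs, mode = network_mode, policy = policy,
                       n_gram_size = n_gram_size)
  if (min_edges > 0) net <- filter_by_degree(net, min_edges = min_edges)
  write_network(net, emit("network.sif"), format = "SIF")
  write_network(net, emit("network.graphml"), format = "GraphML")
  write_node_attributes(net, emit("node_attributes.tsv"))
  message(sprintf("network: %d nodes, %d edges (%s mode)", nrow(net$nodes),
                  nrow(net$edges), network_mode))

  manifest <- list(
    inputs = list(records = records_path,
                  library = library_path %||% "bundled"),
    options = list(policy = policy, n_gram_size = n_gram_size,
                   granularity = granularity, network_mode = network_mode,
                   min_edges = min_edges),
    seed = seed,
    package_version = as.character(utils::packageVersion("rinpep")),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
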