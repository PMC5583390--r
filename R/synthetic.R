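# Seeded generator of synthetic gene-cluster record sets: clusters derived
# from a template compound backbone with module-level corruption, so every
# pipeline stage is testable without genome downloads and the
# identity-versus-correctness relationship can be reproduced.

#' Configuration for the synthetic cluster generator
#'
#' Each simulated cluster copies the template backbone and corrupts
#' modules in two ways that mirror how real predictions fail: predictor
#' discordance (three different calls, so the consensus collapses to the
#' unresolved `nrp` token) and a unanimous wrong call (all three
#' predictors agree on a decoy monomer). The configured rates are the
#' per-module corruption probabilities at 0% genomic identity; each
#' cluster's effective rates scale linearly with its assigned identity
#' level, `rate * (100 - identity) / 100`, so clusters fully identical to
#' the template are corruption-free.
#'
#' @param template A `compound_entry` whose backbone seeds every cluster.
#' @param n_clusters Number of clusters to simulate.
#' @param identity_levels Identity percentages in \[0, 100\], assigned to
#'   clusters in rotation.
#' @param wrong_monomer_rate Base probability of a unanimous decoy call.
#' @param nrp_rate Base probability of predictor discordance.
#' @param vocabulary Decoy monomer tokens (must exclude `"nrp"`, at least
#'   3 for discordant triples).
#' @param seed Integer seed; equal seeds give identical record sets.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(template = default_compound_library()[["Delftibactin"]],
                         n_clusters = 20,
                         identity_levels = c(100, 75, 50, 25),
                         wrong_monomer_rate = 0.1,
                         nrp_rate = 0.2,
                         vocabulary = c("ala", "val", "leu", "ile", "phe",
                                        "trp", "glu", "gln", "lys", "pro"),
                         seed = 1L) {
  if (wrong_monomer_rate < 0 || nrp_rate < 0 ||
      wrong_monomer_rate + nrp_rate > 1) {
    stop("corruption rates must be nonnegative with sum <= 1", call. = FALSE)
  }
  if ("nrp" %in% vocabulary) {
    stop("decoy vocabulary must not contain 'nrp'", call. = FALSE)
  }
  if (length(vocabulary) < 3L) {
    stop("need at least 3 decoy tokens for discordant predictor triples",
         call. = FALSE)
  }
  if (any(identity_levels < 0 | identity_levels > 100)) {
    stop("identity_levels must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(inherits(template, "compound_entry"), n_clusters >= 1)
  structure(list(template = template, n_clusters = as.integer(n_clusters),
                 identity_levels = identity_levels,
                 wrong_monomer_rate = wrong_monomer_rate,
                 nrp_rate = nrp_rate, vocabulary = vocabulary,
                 seed = as.integer(seed)),
            class = "synth_config")
}

unanimous <- function(token) {
  stats::setNames(rep(token, 3L), predictor_names())
}

simulate_modules <- function(tokens, p_nrp, p_wrong, vocabulary) {
  lapply(tokens, function(t) {
    u <- stats::runif(1)
    if (u < p_nrp) {
      # three discordant calls: the consensus collapses to nrp
      stats::setNames(sample(vocabulary, 3L), predictor_names())
    } else if (u < p_nrp + p_wrong) {
      decoys <- setdiff(vocabulary, t)
      unanimous(sample(decoys, 1L))
    } else {
      unanimous(t)
    }
  })
}

#' Simulate a record set from a template compound
#'
#' Corruption acts per module before the consensus call, so `nrp` tokens
#' arise mechanistically from predictor discordance rather than being
#' injected into the backbone. Identity levels are assigned in rotation
#' and recorded as each cluster's `known_match` identity; corruption
#' probabilities scale linearly with `1 - identity/100` (see
#' [synth_config()]). Fully reproducible from the seed.
#'
#' @param cfg A [synth_config()].
#' @return A [record_set()] whose records all carry the template compound
#'   as their known match.
#' @export
simulate_records <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  tokens <- cfg$template$backbone$tokens
  k <- length(cfg$identity_levels)
  records <- lapply(seq_len(cfg$n_clusters), function(i) {
    identity <- cfg$identity_levels[((i - 1L) %% k) + 1L]
    scale <- (100 - identity) / 100
    cluster_record(
      organism = sprintf("synth_organism_%04d", i),
      genome_accession = sprintf("SYN_%06d", i),
      cluster_index = 1L,
      cluster_type = if (any(c("pk", default_pk_class()) %in% tokens))
        "NRPS-T1PKS" else "NRPS",
      modules = simulate_modules(tokens,
                                 p_nrp = cfg$nrp_rate * scale,
                                 p_wrong = cfg$wrong_monomer_rate * scale,
                                 vocabulary = cfg$vocabulary),
      known_match = list(compound_name = cfg$template$name,
                         mibig_id = cfg$template$mibig_id,
                         identity_percent = identity)
    )
  })
  record_set(records,
             provenance = sprintf("simulate_records(seed=%d, n=%d)",
                                  cfg$seed, cfg$n_clusters))
}

#' Simulate a cohort containing divergent outliers
#'
#' Generates a faithful cohort with [simulate_records()], then relabels a
#' chosen fraction of clusters as outliers: they keep (indeed are set to)
#' the highest configured identity level, but their modules are
#' re-simulated under full-strength corruption (the base rates,
#' unscaled) — clusters annotated as near-identical to a known compound
#' whose predictions nonetheless diverge, the situation
#' identity-versus-correctness plots expose.
#'
#' @param cfg A [synth_config()].
#' @param divergent_fraction Fraction of clusters turned into outliers,
#'   in \[0, 1\]. 0 returns exactly [simulate_records()]'s output.
#' @return A [record_set()]; outlier keys are listed in attribute
#'   `outliers`.
#' @export
simulate_outlier <- function(cfg, divergent_fraction) {
  stopifnot(divergent_fraction >= 0, divergent_fraction <= 1)
  rs <- simulate_records(cfg)
  n_out <- round(divergent_fraction * cfg$n_clusters)
  if (n_out == 0L) {
    attr(rs, "outliers") <- character(0)
    return(rs)
  }
  idx <- sample(cfg$n_clusters, n_out)
  tokens <- cfg$template$backbone$tokens
  for (i in idx) {
    r <- rs$records[[i]]
    r$modules <- simulate_modules(tokens, p_nrp = cfg$nrp_rate,
                                  p_wrong = cfg$wrong_monomer_rate,
                                  vocabulary = cfg$vocabulary)
    r$known_match$identity_percent <- max(cfg$identity_levels)
    rs$records[[i]] <- r
  }
  attr(rs, "outliers") <- vapply(rs$records[idx], cluster_key, character(1))
  rs
}
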