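# Shared fixtures and independent oracles, built in code.

delftibactin <- function() {
  default_compound_library()[["Delftibactin"]]
}

# Unanimous predictor calls for one module.
una <- function(token) {
  setNames(rep(token, 3L), predictor_names())
}

# Three discordant calls: consensus collapses to nrp under both policies.
discord <- function(tokens = c("ser", "gly", "thr")) {
  setNames(tokens, predictor_names())
}

# Record whose consensus backbone is exactly `tokens` ("nrp" entries are
# realized as discordant modules).
make_record <- function(tokens, organism = "test organism", index = 1L,
                        compound = NULL, identity = NULL,
                        cluster_type = "NRPS") {
  modules <- lapply(tokens, function(t) {
    if (t == "nrp") discord() else una(t)
  })
  km <- if (!is.null(compound)) {
    list(compound_name = compound, mibig_id = NA_character_,
         identity_percent = identity)
  }
  cluster_record(organism = organism, cluster_index = index,
                 cluster_type = cluster_type, modules = modules,
                 known_match = km)
}

# --- independent oracles ----------------------------------------------

# Three-way match classification by direct enumeration over backbone
# adjacencies, written without reference to match_pop's internals.
oracle_match <- function(tok1, tok2, backbone_tokens, pk_members) {
  map1 <- function(t) if (t %in% pk_members) "pk" else t
  b <- vapply(backbone_tokens, map1, character(1))
  m1 <- map1(tok1); m2 <- map1(tok2)
  L <- length(b)
  for (i in seq_len(max(L - 1L, 0L))) {
    if ((b[i] == m1 && b[i + 1L] == m2) || (b[i] == m2 && b[i + 1L] == m1)) {
      return("exact")
    }
  }
  n_nrp <- (m1 == "nrp") + (m2 == "nrp")
  other <- c(m1, m2)[c(m1, m2) != "nrp"]
  if (n_nrp == 1L && L >= 2L && other %in% b) {
    return("partial_nrp")
  }
  "none"
}

# Naive agglomerative average linkage: O(n^3) loops over explicit
# Euclidean distances, returning the multiset of merge heights.
oracle_average_linkage_heights <- function(m) {
  eucl <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- eucl(i, j)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- clusters[-c(bi, bj)]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Brute-force Jaccard over explicit element loops.
oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0L
  for (x in a) if (x %in% b) inter <- inter + 1L
  uni <- length(unique(c(a, b)))
  if (uni == 0L) 0 else inter / uni
}
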