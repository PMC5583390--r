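# Backbones and their canonical n-gram fragments: POPs from predictions,
# PECs from known compounds.

#' Construct a backbone
#'
#' An ordered monomer chain — either the predicted core structure of a gene
#' cluster or the backbone of a known compound. Order is the biosynthetic
#' chain order as given; fragmentation is linear, so no fragment joins the
#' terminal monomer back to the start even for compounds drawn with a
#' cyclized terminus.
#'
#' @param tokens Character vector of raw or canonical monomer tokens;
#'   normalized on construction.
#' @param source_kind `"predicted"` or `"known_compound"`.
#' @param source_id Compound name or genome+cluster key.
#' @param normalize Set `FALSE` when tokens are already canonical.
#' @return Object of class `rinpep_backbone` with fields `tokens`
#'   (canonical), `modifications` (list, per position), `source_kind`,
#'   `source_id`.
#' @export
backbone <- function(tokens, source_kind = c("predicted", "known_compound"),
                     source_id = NA_character_, normalize = TRUE) {
  source_kind <- match.arg(source_kind)
  if (length(tokens) < 1L) stop("backbone needs at least one monomer", call. = FALSE)
  mods <- vector("list", length(tokens))
  if (normalize) {
    mono <- lapply(tokens, normalize_monomer)
    tokens <- vapply(mono, `[[`, character(1), "token")
    mods <- lapply(mono, `[[`, "modifications")
  } else {
    tokens <- as_token(tokens)
  }
  structure(list(tokens = tokens, modifications = mods,
                 source_kind = source_kind, source_id = source_id),
            class = "rinpep_backbone")
}

backbone_tokens <- function(b) {
  if (inherits(b, "rinpep_backbone")) b$tokens else as_token(b)
}

#' @export
print.rinpep_backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s (%s, %d monomers)\n  %s\n",
              x$source_id, x$source_kind, length(x$tokens),
              paste(x$tokens, collapse = " + ")))
  invisible(x)
}

#' Canonical alphabetized monomer pair
#'
#' The unit of all pattern analysis: two monomer tokens joined as
#' `"a.b"` with the tokens in lexicographic order, so the key is invariant
#' under swapping the arguments. The chemical rationale is that a
#' two-monomer fragment is identified in a mass or NMR spectrum regardless
#' of its orientation in the chain. Vectorized.
#'
#' @param a,b Monomers or canonical token vectors.
#' @return Character vector of pair keys.
#' @examples
#' canonical_pair("val", "ala")  # "ala.val"
#' @export
canonical_pair <- function(a, b) {
  a <- as_token(a)
  b <- as_token(b)
  paste(pmin(a, b), pmax(a, b), sep = ".")
}

#' Build a pair multiset from fragment keys
#'
#' @param keys Character vector of canonical fragment keys (with
#'   repetitions).
#' @param origin Source identifier carried along for reporting.
#' @return Named integer vector (key -> multiplicity), keys sorted, class
#'   `pair_multiset` with attribute `origin`.
#' @export
pair_multiset <- function(keys, origin = NA_character_) {
  counts <- if (length(keys)) {
    tab <- table(keys)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(counts[order(names(counts))], origin = origin, class = "pair_multiset")
}

#' @export
print.pair_multiset <- function(x, ...) {
  cat(sprintf("<pair multiset> origin=%s, %d unique / %d total\n",
              attr(x, "origin"), length(x), sum(x)))
  if (length(x)) {
    cat(" ", paste(sprintf("%s:%d", names(x), x), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Fragment a backbone into canonical n-grams
#'
#' Slides a window of `n_gram_size` adjacent monomers along the chain and
#' canonicalizes each window by alphabetical sorting. The default size 2
#' produces the pairs used throughout (POPs/PECs): a backbone of length L
#' yields exactly L-1 fragments counting multiplicity. Sizes 1 and 3 give
#' single-monomer and triad fingerprints for sensitivity comparison.
#' Fragmentation is linear: no wrap-around fragment is emitted for
#' cyclized termini.
#'
#' @param b A [backbone()] or character vector of canonical tokens.
#' @param n_gram_size 1, 2 (default) or 3.
#' @return A [pair_multiset()]. A backbone shorter than `n_gram_size`
#'   yields an empty multiset with attribute `short = TRUE` and a warning.
#' @examples
#' fragment_backbone(backbone(c("ala", "val", "orn", "ser"), source_id = "toy"))
#' @export
fragment_backbone <- function(b, n_gram_size = 2) {
  if (!is.numeric(n_gram_size) || length(n_gram_size) != 1L ||
      !n_gram_size %in% 1:3) {
    stop("n_gram_size must be 1, 2 or 3", call. = FALSE)
  }
  toks <- backbone_tokens(b)
  origin <- if (inherits(b, "rinpep_backbone")) b$source_id else NA_character_
  L <- length(toks)
  if (L < n_gram_size) {
    warning(sprintf("backbone '%s' shorter than n-gram size %d: no fragments",
                    origin, n_gram_size), call. = FALSE)
    ms <- pair_multiset(character(0), origin = origin)
    attr(ms, "short") <- TRUE
    return(ms)
  }
  keys <- switch(as.character(n_gram_size),
    "1" = toks,
    "2" = canonical_pair(toks[-L], toks[-1L]),
    "3" = vapply(seq_len(L - 2L), function(i) {
      paste(sort(toks[i:(i + 2L)]), collapse = ".")
    }, character(1))
  )
  pair_multiset(keys, origin = origin)
}

#' Unique-set view of a pair multiset
#'
#' The support of the multiset — each pair once, multiplicities dropped.
#' Binary matrices and Jaccard indices use this view; distribution tables
#' use the multiplicities.
#'
#' @param ms A [pair_multiset()].
#' @return Character vector of pair keys.
#' @export
unique_pairs <- function(ms) {
  names(ms)
}

#' Write / read pair multisets as TSV
#'
#' Three columns: `origin`, `pair_key`, `count`.
#'
#' @param x A single [pair_multiset()] or a list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pair_multisets <- function(x, path) {
  if (inherits(x, "pair_multiset")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(ms) {
    if (!length(ms)) return(NULL)
    data.frame(origin = attr(ms, "origin"), pair_key = names(ms),
               count = as.integer(ms), stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(origin = character(0), pair_key = character(0),
                       count = integer(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_multisets
#' @export
read_pair_multisets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  lapply(split(tab, tab$origin), function(d) {
    pair_multiset(rep(d$pair_key, d$count), origin = d$origin[1])
  })
}
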