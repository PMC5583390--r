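# Canonical monomer vocabulary, modification stripping, three-predictor
# consensus calling and polyketide-class mapping.

.rinpep_cache <- new.env(parent = emptyenv())

#' Names of the three adenylation-domain specificity predictors
#'
#' Monomer calls are taken from the three predictors reported in antiSMASH
#' v3-era output. Every module of a cluster record carries exactly these
#' three slots; an absent call is `NA`, never an empty string.
#'
#' @return Character vector of the three predictor names.
#' @export
predictor_names <- function() {
  c("NRPSpredictor2", "Stachelhaus", "Minowa")
}

#' Construct a monomer
#'
#' A monomer is a single building block incorporated by one NRPS (or hybrid
#' PKS) module: a lowercase canonical token plus any modification tags
#' stripped from the raw annotation (e.g. `mod`, `cyclic`, `NH2`). The token
#' `"nrp"` is the unresolved placeholder used when the predictors disagree
#' and the side chain cannot be assigned. Modifications never affect
#' equality: two monomers with equal tokens compare equal.
#'
#' @param token Canonical lowercase token (no whitespace, no `"."`).
#' @param modifications Character vector of stripped annotation tags.
#' @param pk_table Polyketide class table used to set `kind`, see
#'   [default_pk_class()].
#' @return An object of class `rinpep_monomer` with fields `token`, `kind`
#'   (one of `amino_acid`, `polyketide`, `unresolved`) and `modifications`.
#' @export
monomer <- function(token, modifications = character(),
                    pk_table = default_pk_class()) {
  token <- as.character(token)
  if (length(token) != 1L || is.na(token) || !nzchar(token)) {
    stop("monomer token must be a single nonempty string", call. = FALSE)
  }
  if (grepl("[[:space:].]", token) || token != tolower(token)) {
    stop(sprintf("invalid monomer token '%s': must be lowercase with no whitespace or '.'", token),
         call. = FALSE)
  }
  kind <- if (token == "nrp") {
    "unresolved"
  } else if (token %in% pk_table) {
    "polyketide"
  } else {
    "amino_acid"
  }
  structure(list(token = token, kind = kind,
                 modifications = as.character(modifications)),
            class = "rinpep_monomer")
}

#' @export
print.rinpep_monomer <- function(x, ...) {
  mods <- if (length(x$modifications)) {
    paste0(" [", paste(x$modifications, collapse = ","), "]")
  } else ""
  cat(sprintf("<monomer> %s (%s)%s\n", x$token, x$kind, mods))
  invisible(x)
}

#' @export
`==.rinpep_monomer` <- function(e1, e2) {
  as_token(e1) == as_token(e2)
}

# Accept a monomer object, a list of them, or a plain character vector and
# return canonical token(s).
as_token <- function(x) {
  if (inherits(x, "rinpep_monomer")) return(x$token)
  if (is.list(x)) return(vapply(x, as_token, character(1)))
  as.character(x)
}

#' Bundled raw-to-canonical monomer synonym table
#'
#' Spelling variants across the antiSMASH, KEGG and Norine nomenclatures are
#' reconciled through an editable two-column TSV (`raw`, `canonical`)
#' shipped with the package; users can extend it without code changes and
#' pass their own table to [normalize_monomer()].
#'
#' @param path Path to a two-column TSV; defaults to the bundled table.
#' @return Named character vector mapping lowercase raw spellings to
#'   canonical tokens.
#' @export
load_synonyms <- function(path = system.file("extdata", "monomer_synonyms.tsv",
                                             package = "rinpep")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("raw", "canonical") %in% names(tab))) {
    stop("synonym table must have columns 'raw' and 'canonical'", call. = FALSE)
  }
  stats::setNames(tolower(tab$canonical), tolower(tab$raw))
}

default_synonyms <- function() {
  if (is.null(.rinpep_cache$synonyms)) {
    .rinpep_cache$synonyms <- load_synonyms()
  }
  .rinpep_cache$synonyms
}

#' Polyketide class table
#'
#' Tokens treated as one polyketide class for pair comparison. Hybrid
#' NRPS-PKS products carry polyketide-derived units whose specific acyl
#' token (e.g. `ohmal`, `mal`, `mmal`) and the generic `pk` token name the
#' same backbone portion; the class table reconciles them. Membership is a
#' one-column TSV (`token`) so the vocabulary is configuration, not code.
#'
#' @param path Path to the one-column TSV; defaults to the bundled table.
#' @return Character vector of member tokens with attribute `class_token`
#'   (`"pk"`), class `pk_class_table`.
#' @export
load_pk_class <- function(path = system.file("extdata", "pk_class.tsv",
                                             package = "rinpep")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  members <- tolower(trimws(tab[[1]]))
  class_token <- "pk"
  if (!class_token %in% members) {
    stop("polyketide class table must contain the class token 'pk'", call. = FALSE)
  }
  structure(members, class_token = class_token, class = "pk_class_table")
}

#' @rdname load_pk_class
#' @export
default_pk_class <- function() {
  if (is.null(.rinpep_cache$pk_class)) {
    .rinpep_cache$pk_class <- load_pk_class()
  }
  .rinpep_cache$pk_class
}

#' Normalize a raw monomer token
#'
#' Trims whitespace, strips parenthesized modification annotations into the
#' `modifications` field (compound annotations split on `+`, e.g.
#' `"pk(NH2+ohmal)"` gives tags `NH2` and `ohmal`), lowercases, and maps the
#' result through the synonym table. Normalization is idempotent.
#'
#' @param raw_token Raw monomer spelling, e.g. `"Orn(cyclic)"`.
#' @param synonyms Synonym map from [load_synonyms()].
#' @param pk_table Polyketide class table.
#' @return A [monomer()].
#' @examples
#' normalize_monomer("Orn(cyclic)")  # token "orn", modification "cyclic"
#' normalize_monomer("Thr(mod)")
#' @export
normalize_monomer <- function(raw_token, synonyms = default_synonyms(),
                              pk_table = default_pk_class()) {
  if (length(raw_token) != 1L) {
    stop("normalize_monomer() takes a single token; vapply over vectors", call. = FALSE)
  }
  tok <- trimws(as.character(raw_token))
  if (is.na(tok) || !nzchar(tok)) {
    stop("empty monomer token", call. = FALSE)
  }
  mods <- character()
  while (grepl("\\(([^()]*)\\)", tok)) {
    ann <- sub(".*?\\(([^()]*)\\).*", "\\1", tok, perl = TRUE)
    mods <- c(mods, trimws(strsplit(ann, "+", fixed = TRUE)[[1]]))
    tok <- sub("\\(([^()]*)\\)", "", tok)
  }
  tok <- tolower(trimws(tok))
  hit <- match(tok, names(synonyms))
  if (!is.na(hit)) tok <- unname(synonyms[hit])
  if (!nzchar(tok) || grepl("[[:space:].]", tok)) {
    stop(sprintf("cannot normalize monomer token '%s'", raw_token), call. = FALSE)
  }
  monomer(tok, modifications = mods[nzchar(mods)], pk_table = pk_table)
}

# Vectorized token-only normalization used on ingest and in fragmentation.
normalize_tokens <- function(raw, synonyms = default_synonyms()) {
  vapply(raw, function(x) normalize_monomer(x, synonyms = synonyms)$token,
         character(1), USE.NAMES = FALSE)
}

#' Consensus monomer call across the three predictors
#'
#' A module's monomer is accepted only when the predictors agree; any
#' incongruence between them yields the unresolved placeholder `"nrp"`,
#' meaning the R group could not be assigned. Under the default `"strict"`
#' policy all three calls must be present and identical after
#' normalization; under `"majority"` two matching calls suffice. An absent
#' call (`NA`) counts as non-matching. The result never lies outside the
#' set of normalized input tokens plus `"nrp"`, and is insensitive to the
#' order of the predictor slots.
#'
#' @param calls Named list or character vector with exactly the three slots
#'   of [predictor_names()] (any order); values are raw tokens or `NA`.
#' @param policy `"strict"` (unanimity, default) or `"majority"` (2 of 3).
#' @param synonyms,pk_table Normalization tables.
#' @return A [monomer()]: the agreed token, or the unresolved `"nrp"`.
#' @export
consensus_call <- function(calls, policy = c("strict", "majority"),
                           synonyms = default_synonyms(),
                           pk_table = default_pk_class()) {
  policy <- match.arg(policy)
  calls <- unlist(calls)
  expected <- predictor_names()
  if (length(calls) != 3L || is.null(names(calls)) ||
      !setequal(names(calls), expected)) {
    stop("calls must carry exactly the three predictor slots: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  toks <- rep(NA_character_, 3L)
  present <- !is.na(calls) & nzchar(trimws(calls))
  toks[present] <- normalize_tokens(calls[present], synonyms = synonyms)
  agreed <- if (policy == "strict") {
    if (all(present) && length(unique(toks)) == 1L) toks[1] else "nrp"
  } else {
    counts <- table(toks[present])
    top <- names(counts)[counts >= 2L]
    if (length(top) == 1L) top else "nrp"
  }
  monomer(agreed, pk_table = pk_table)
}

#' Map a monomer token onto the polyketide comparison class
#'
#' Before POPs and PECs are compared, every polyketide-class token is
#' collapsed to the generic class token `"pk"`, so that e.g. a predicted
#' `ohmal` unit and a backbone drawn with a generic `pk` unit name the same
#' hybrid-pathway portion. Non-members pass through unchanged. Vectorized.
#'
#' @param m A monomer, list of monomers, or character vector of tokens.
#' @param table Polyketide class table, see [load_pk_class()].
#' @return Character vector of comparison tokens.
#' @examples
#' pk_classify(c("ohmal", "pk", "ser"))  # "pk" "pk" "ser"
#' @export
pk_classify <- function(m, table = default_pk_class()) {
  tok <- tolower(as_token(m))
  ifelse(tok %in% table, attr(table, "class_token"), tok)
}
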