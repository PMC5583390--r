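# Library of known nonribosomal peptides as ordered monomer backbones and
# their PEC (pair-of-existent-compound) sets.

#' Load a compound library
#'
#' The library is a TSV with columns `name`, `mibig_id`, `backbone`
#' (comma-separated raw monomer tokens, modifications in parentheses, e.g.
#' `pk(NH2+ohmal),Asp,Thr,...`) and `citation`, so a backbone drawn in the
#' literature can be transcribed verbatim. The bundled default contains
#' Delftibactin (MIBiG BGC0000984), the hybrid NRPS-PKS metallophore used
#' as the validation template; further compounds (e.g. Malleobactin,
#' tridecaptins) are supplied by the user in the same format.
#'
#' @param path Library TSV; defaults to the bundled library.
#' @return Object of class `compound_library`: a named list of
#'   `compound_entry` objects (`name`, `mibig_id`, `backbone`,
#'   `raw_backbone`, `citation`).
#' @export
load_compound_library <- function(path = system.file("extdata", "compound_library.tsv",
                                                     package = "rinpep")) {
  if (!file.exists(path)) stop("compound library not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(structure(stats::setNames(list(), character(0)),
                     class = "compound_library"))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  required <- c("name", "mibig_id", "backbone", "citation")
  if (!all(required %in% names(tab))) {
    stop("compound library must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(tab$name[duplicated(tab$name)])
  if (length(dup)) {
    stop("duplicate compound names in library: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (nzchar(row$mibig_id) && !grepl("^BGC[0-9]{7}", row$mibig_id)) {
      stop(sprintf("line %d (%s): malformed MIBiG id '%s'", i + 1L, row$name,
                   row$mibig_id), call. = FALSE)
    }
    raw <- trimws(strsplit(row$backbone, ",", fixed = TRUE)[[1]])
    bb <- tryCatch(
      backbone(raw, source_kind = "known_compound", source_id = row$name),
      error = function(e) stop(sprintf("line %d (%s): %s", i + 1L, row$name,
                                       conditionMessage(e)), call. = FALSE)
    )
    structure(list(name = row$name, mibig_id = row$mibig_id, backbone = bb,
                   raw_backbone = raw, citation = row$citation),
              class = "compound_entry")
  })
  structure(stats::setNames(entries, tab$name), class = "compound_library")
}

#' @rdname load_compound_library
#' @export
default_compound_library <- function() {
  load_compound_library()
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("<compound library> %d entries: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Write a compound library back to TSV
#'
#' Emits the same four-column format [load_compound_library()] reads, using
#' the raw backbone spellings so modification annotations survive a
#' round trip.
#'
#' @param lib A `compound_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(lib, path) {
  tab <- data.frame(
    name = vapply(lib, `[[`, character(1), "name"),
    mibig_id = vapply(lib, `[[`, character(1), "mibig_id"),
    backbone = vapply(lib, function(e) paste(e$raw_backbone, collapse = ","),
                      character(1)),
    citation = vapply(lib, `[[`, character(1), "citation"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' PEC set of a known compound
#'
#' Fragments the compound backbone into its pairs of existent compound
#' (PECs). Delegates to [fragment_backbone()], so the multiset counts
#' repeated pairs (Delftibactin's `gly.thr` occurs twice among its eight
#' fragments) while [unique_pairs()] gives the seven-pair support used for
#' matching.
#'
#' @param entry A `compound_entry`.
#' @param n_gram_size Fragment size, default 2.
#' @return A [pair_multiset()].
#' @export
pecs_for <- function(entry, n_gram_size = 2) {
  stopifnot(inherits(entry, "compound_entry"))
  fragment_backbone(entry$backbone, n_gram_size = n_gram_size)
}
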