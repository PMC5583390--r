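# Reading, validating and writing BGC prediction records, and deriving
# each record's POPs (pairs of predictions).

#' Construct and validate a cluster record
#'
#' One biosynthetic gene cluster: organism, cluster index, cluster type,
#' the ordered per-module calls of the three predictors, and the optional
#' most-similar-known-cluster annotation from MIBiG. Records from draft
#' genomes may carry no modules; they are retained but contribute no POPs,
#' mirroring the natural filtering of predictions without a core structure.
#' `identity_percent` is the percent of genes showing homology to the
#' known cluster, carried verbatim.
#'
#' @param organism Organism name.
#' @param cluster_index Positive integer cluster number within the genome.
#' @param cluster_type e.g. `"NRPS"`, `"NRPS-T1PKS"`.
#' @param modules List of named length-3 character vectors (one per
#'   module, names = [predictor_names()], `NA` for an absent call).
#' @param genome_accession Optional accession.
#' @param known_match `NULL`, or a list with `compound_name`, `mibig_id`,
#'   `identity_percent` in \[0, 100\].
#' @return Object of class `cluster_record`.
#' @export
cluster_record <- function(organism, cluster_index, cluster_type, modules,
                           genome_accession = NA_character_,
                           known_match = NULL) {
  if (!is.character(organism) || length(organism) != 1L || !nzchar(organism)) {
    stop("organism must be a nonempty string", call. = FALSE)
  }
  cluster_index <- as.integer(cluster_index)
  if (is.na(cluster_index) || cluster_index < 1L) {
    stop(sprintf("record '%s': cluster_index must be a positive integer", organism),
         call. = FALSE)
  }
  expected <- predictor_names()
  modules <- lapply(seq_along(modules), function(i) {
    m <- unlist(modules[[i]])
    m[!nzchar(trimws(m))] <- NA_character_
    extra <- setdiff(names(m), expected)
    if (length(extra)) {
      stop(sprintf("record '%s' module %d: unknown predictor name(s): %s",
                   organism, i, paste(extra, collapse = ", ")), call. = FALSE)
    }
    full <- stats::setNames(rep(NA_character_, 3L), expected)
    full[names(m)] <- m
    present <- !is.na(full)
    full[present] <- vapply(which(present), function(j) {
      tryCatch(normalize_monomer(full[[j]])$token, error = function(e) {
        stop(sprintf("record '%s' module %d (%s): %s", organism, i,
                     expected[j], conditionMessage(e)), call. = FALSE)
      })
    }, character(1))
    full
  })
  if (!is.null(known_match)) {
    ip <- suppressWarnings(as.numeric(known_match$identity_percent))
    if (is.null(known_match$compound_name) || length(ip) != 1L || is.na(ip) ||
        ip < 0 || ip > 100) {
      stop(sprintf("record '%s': known_match needs compound_name and identity_percent in [0,100]",
                   organism), call. = FALSE)
    }
    known_match <- list(
      compound_name = as.character(known_match$compound_name),
      mibig_id = if (is.null(known_match$mibig_id) ||
                     is.na(known_match$mibig_id) ||
                     !nzchar(known_match$mibig_id)) NA_character_ else
        as.character(known_match$mibig_id),
      identity_percent = ip
    )
  }
  structure(list(organism = organism,
                 genome_accession = as.character(genome_accession),
                 cluster_index = cluster_index,
                 cluster_type = as.character(cluster_type),
                 modules = modules,
                 known_match = known_match),
            class = "cluster_record")
}

#' Key identifying a cluster record
#'
#' `"<organism>-C<index>"`, e.g. `"B. caribensis-C9"`; falls back to the
#' genome accession when the organism name is missing.
#'
#' @param r A `cluster_record`.
#' @return Single string.
#' @export
cluster_key <- function(r) {
  base <- if (!is.na(r$organism) && nzchar(r$organism)) r$organism else
    r$genome_accession
  sprintf("%s-C%d", base, r$cluster_index)
}

#' Bundle validated records into a record set
#'
#' @param records List of [cluster_record()]s.
#' @param provenance Free-text description of where the records came from.
#' @return Object of class `record_set`. Duplicate cluster keys are an
#'   error.
#' @export
record_set <- function(records, provenance = "") {
  keys <- vapply(records, cluster_key, character(1))
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) {
    stop("duplicate cluster keys: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(records = records, provenance = provenance),
            class = "record_set")
}

#' @export
print.record_set <- function(x, ...) {
  n_mod <- vapply(x$records, function(r) length(r$modules), integer(1))
  cat(sprintf("<record set> %d clusters (%d without modules)\n",
              length(x$records), sum(n_mod == 0L)))
  invisible(x)
}

#' @export
length.record_set <- function(x) length(x$records)

module_to_list <- function(m) {
  lapply(as.list(m), function(v) if (is.na(v)) NULL else v)
}

#' Read cluster records from JSON or TSV
#'
#' The canonical input is a versioned JSON array (schema shipped at
#' `inst/extdata/cluster_records_schema.json`); an equivalent flat TSV
#' dialect is accepted, with modules encoded as `;`-separated triples
#' `call1/call2/call3` in [predictor_names()] order and `-` for an absent
#' call. All monomer tokens are normalized on ingest; validation failures
#' name the record and module. A bundled illustrative example is at
#' `system.file("extdata", "example_clusters.json", package = "rinpep")`.
#'
#' @param path Input file (`.json` or `.tsv`).
#' @param format `"auto"` (by extension), `"json"` or `"tsv"`.
#' @return A [record_set()].
#' @export
read_cluster_records <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    records <- lapply(seq_along(raw), function(i) {
      r <- raw[[i]]
      for (f in c("organism", "cluster_index", "cluster_type")) {
        if (is.null(r[[f]])) {
          stop(sprintf("record %d: missing required field '%s'", i, f),
               call. = FALSE)
        }
      }
      modules <- lapply(r$modules, function(m) {
        vapply(predictor_names(), function(p) {
          v <- m[[p]]
          if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
        }, character(1))
      })
      # reject modules carrying slots outside the three predictors
      bad <- unlist(lapply(r$modules, function(m) setdiff(names(m), predictor_names())))
      if (length(bad)) {
        stop(sprintf("record %d (%s): unknown predictor name(s): %s", i,
                     r$organism, paste(unique(bad), collapse = ", ")), call. = FALSE)
      }
      cluster_record(organism = r$organism,
                     cluster_index = r$cluster_index,
                     cluster_type = r$cluster_type,
                     modules = modules,
                     genome_accession = r$genome_accession %||% NA_character_,
                     known_match = r$known_match)
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                             colClasses = "character")
    records <- lapply(seq_len(nrow(tab)), function(i) {
      row <- tab[i, ]
      modules <- if (nzchar(row$modules)) {
        lapply(strsplit(row$modules, ";", fixed = TRUE)[[1]], function(triple) {
          calls <- strsplit(triple, "/", fixed = TRUE)[[1]]
          if (length(calls) != 3L) {
            stop(sprintf("record %d: module '%s' is not a call1/call2/call3 triple",
                         i, triple), call. = FALSE)
          }
          calls[calls == "-"] <- NA_character_
          stats::setNames(calls, predictor_names())
        })
      } else list()
      km <- if (nzchar(row$compound_name)) {
        list(compound_name = row$compound_name, mibig_id = row$mibig_id,
             identity_percent = as.numeric(row$identity_percent))
      } else NULL
      cluster_record(organism = row$organism,
                     cluster_index = as.integer(row$cluster_index),
                     cluster_type = row$cluster_type,
                     modules = modules,
                     genome_accession = row$genome_accession,
                     known_match = km)
    })
  }
  record_set(records, provenance = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cluster records to JSON and/or TSV
#'
#' The JSON writer emits the canonical schema; the TSV writer emits the
#' flat dialect [read_cluster_records()] accepts. A JSON round trip
#' preserves every field.
#'
#' @param rs A [record_set()].
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cluster_records <- function(rs, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- lapply(rs$records, function(r) {
      list(organism = r$organism,
           genome_accession = if (is.na(r$genome_accession)) NULL else r$genome_accession,
           cluster_index = r$cluster_index,
           cluster_type = r$cluster_type,
           modules = lapply(r$modules, module_to_list),
           known_match = r$known_match)
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    tab <- do.call(rbind, lapply(rs$records, function(r) {
      mods <- paste(vapply(r$modules, function(m) {
        m[is.na(m)] <- "-"
        paste(m, collapse = "/")
      }, character(1)), collapse = ";")
      data.frame(organism = r$organism,
                 genome_accession = ifelse(is.na(r$genome_accession), "", r$genome_accession),
                 cluster_index = r$cluster_index,
                 cluster_type = r$cluster_type,
                 modules = mods,
                 compound_name = if (is.null(r$known_match)) "" else r$known_match$compound_name,
                 mibig_id = if (is.null(r$known_match) || is.na(r$known_match$mibig_id)) "" else r$known_match$mibig_id,
                 identity_percent = if (is.null(r$known_match)) "" else
                   format(r$known_match$identity_percent, digits = 15),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' POPs of a cluster record
#'
#' Applies the consensus call to every module (incongruent or absent calls
#' become the unresolved `"nrp"` token) and fragments the resulting
#' predicted core structure into canonical pairs of predictions (POPs).
#' Records with no modules yield an empty multiset flagged `no_pops`.
#'
#' @param r A [cluster_record()].
#' @param policy Consensus policy, see [consensus_call()].
#' @param n_gram_size Fragment size, default 2.
#' @return A [pair_multiset()] with `origin = cluster_key(r)`.
#' @export
pops_for <- function(r, policy = "strict", n_gram_size = 2) {
  key <- cluster_key(r)
  if (!length(r$modules)) {
    ms <- pair_multiset(character(0), origin = key)
    attr(ms, "no_pops") <- TRUE
    return(ms)
  }
  toks <- vapply(r$modules, function(m) consensus_call(m, policy = policy)$token,
                 character(1))
  suppressWarnings(
    fragment_backbone(backbone(toks, source_kind = "predicted",
                               source_id = key, normalize = FALSE),
                      n_gram_size = n_gram_size)
  )
}
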