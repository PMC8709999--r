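## Source inference: attribute a candidate cDNA to a cloning vector or a
## retrocopy from its terminal overhang consensus sequences, via local
## alignment against UniVec-style / RepBase-style FASTA databases (NCBI
## BLAST+ blastn), falling back to clip-distance heuristics when no usable
## hit exists.

blast_available <- function(blastn = "blastn", makeblastdb = "makeblastdb") {
  nzchar(Sys.which(blastn)) && nzchar(Sys.which(makeblastdb))
}

## prepare (and cache) a blast nucleotide db for a FASTA file
.blast_db_cache <- new.env(parent = emptyenv())
prepare_blast_db <- function(fasta, makeblastdb = "makeblastdb") {
  key <- normalizePath(fasta)
  hit <- .blast_db_cache[[key]]
  if (!is.null(hit) && file.exists(paste0(hit, ".nsq"))) return(hit)
  out <- file.path(tempdir(), paste0("blastdb_", abs(sum(utf8ToInt(key))),
                                     "_", basename(fasta)))
  status <- system2(makeblastdb,
                    c("-in", shQuote(fasta), "-dbtype", "nucl",
                      "-out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed for ", fasta)
  .blast_db_cache[[key]] <- out
  out
}

#' Query an overhang consensus against a sequence database
#'
#' Local alignment (blastn) of a clip consensus against a vector or repeat
#' FASTA database; the highest-scoring hit with E-value <= `max_evalue` is
#' returned. Queries shorter than `min_query` bases are below a reliable
#' query length and return `NULL` without searching. When the blastn
#' executable is unavailable, `NULL` is returned with attribute
#' `search_unavailable = TRUE` so inference falls back to clip distances.
#'
#' @param consensus query sequence (natural orientation).
#' @param db path to a FASTA database file.
#' @param max_evalue E-value cutoff (default 10).
#' @param min_query minimum query length searched (default 8).
#' @param blastn,makeblastdb executable names/paths.
#' @return `NULL`, or a list with `subject`, `evalue`, `pident`, `bitscore`,
#'   `length`.
#' @export
query_overhang <- function(consensus, db, max_evalue = 10, min_query = 8L,
                           blastn = "blastn", makeblastdb = "makeblastdb") {
  if (is.null(db) || is.null(consensus) || is.na(consensus) ||
      nchar(consensus) < min_query)
    return(NULL)
  if (!blast_available(blastn, makeblastdb)) {
    out <- NULL
    attr(out, "search_unavailable") <- TRUE
    return(out)
  }
  dbp <- prepare_blast_db(db, makeblastdb)
  qf <- tempfile(fileext = ".fa")
  on.exit(unlink(qf))
  writeLines(c(">query", consensus), qf)
  task <- if (nchar(consensus) < 30L) "blastn-short" else "blastn"
  res <- suppressWarnings(system2(
    blastn,
    c("-query", shQuote(qf), "-db", shQuote(dbp), "-task", task,
      "-evalue", format(max_evalue), "-outfmt",
      shQuote("6 qseqid sseqid pident length evalue bitscore")),
    stdout = TRUE, stderr = FALSE))
  if (!is.null(attr(res, "status")) || length(res) == 0L) return(NULL)
  tab <- utils::read.table(text = res, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("qseqid", "sseqid", "pident",
                                         "length", "evalue", "bitscore"))
  tab <- tab[tab$evalue <= max_evalue, , drop = FALSE]
  if (nrow(tab) == 0L) return(NULL)
  best <- tab[order(-tab$bitscore, tab$evalue), ][1L, ]
  list(subject = best$sseqid, evalue = best$evalue, pident = best$pident,
       bitscore = best$bitscore, length = best$length)
}

#' Infer the origin of a candidate cDNA
#'
#' Decision order: (1) a vector-database hit labels the candidate
#' `"vector"`; (2) a repeat-database hit with representative clip distance
#' > 5 bp labels it `"retrocopy"` (retrocopies typically retain UTR sequence,
#' displacing the clip from the annotated boundary); (3) with no usable hit,
#' the representative distance decides: <= 5 bp `"vector-likely"`,
#' > 10 bp `"retrocopy-likely"`, otherwise `"unknown"`. The representative
#' distance is the median absolute clip-junction offset over both ends. A
#' repeat hit at distance <= 5 bp falls through to the distance heuristic;
#' when the two ends disagree, vector evidence wins.
#'
#' @param consensus_5p,consensus_3p terminal consensus sequences (natural
#'   orientation; may be `""`).
#' @param offsets_5p,offsets_3p signed clip-junction offsets (bp) observed at
#'   the two ends.
#' @param vector_db,repeat_db optional FASTA database paths.
#' @param ... passed to [query_overhang()].
#' @return list of class `source_call` with `label` (one of `vector`,
#'   `retrocopy`, `vector-likely`, `retrocopy-likely`, `unknown`) and
#'   `evidence`.
#' @export
infer_source <- function(consensus_5p = "", consensus_3p = "",
                         offsets_5p = integer(0), offsets_3p = integer(0),
                         vector_db = NULL, repeat_db = NULL, ...) {
  dist <- stats::median(abs(c(offsets_5p, offsets_3p)))
  ev <- list(db_hit = NULL, clip_distance = dist)

  vhit <- best_of(query_overhang(consensus_5p, vector_db, ...),
                  query_overhang(consensus_3p, vector_db, ...))
  if (!is.null(vhit)) {
    ev$db_hit <- c(database = "vector", subject = vhit$subject,
                   evalue = vhit$evalue)
    return(structure(list(label = "vector", evidence = ev),
                     class = "source_call"))
  }
  rhit <- best_of(query_overhang(consensus_5p, repeat_db, ...),
                  query_overhang(consensus_3p, repeat_db, ...))
  if (!is.null(rhit) && !is.na(dist) && dist > 5) {
    ev$db_hit <- c(database = "repeat", subject = rhit$subject,
                   evalue = rhit$evalue)
    return(structure(list(label = "retrocopy", evidence = ev),
                     class = "source_call"))
  }
  label <- if (is.na(dist)) "unknown"
           else if (dist <= 5) "vector-likely"
           else if (dist > 10) "retrocopy-likely"
           else "unknown"
  structure(list(label = label, evidence = ev), class = "source_call")
}

best_of <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (b$bitscore > a$bitscore) b else a
}

#' @export
print.source_call <- function(x, ...) {
  cat("source_call:", x$label)
  if (!is.null(x$evidence$db_hit))
    cat(" (", x$evidence$db_hit[["database"]], " hit ",
        x$evidence$db_hit[["subject"]], ", E = ",
        x$evidence$db_hit[["evalue"]], ")", sep = "")
  if (!is.na(x$evidence$clip_distance))
    cat(" [median clip distance ", x$evidence$clip_distance, " bp]", sep = "")
  cat("\n")
  invisible(x)
}
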