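# Sequence I/O: FASTA/FASTQ readers and writers (via Biostrings), paired-end
# interleaving, and a bounded-memory batch stream with buffer shuffling.

clean_sequences <- function(ids, seqs, path) {
  if (length(seqs) == 0) stop("empty sequence file: ", path, call. = FALSE)
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)][1]
    stop("record with empty sequence: '", bad, "' in ", path, call. = FALSE)
  }
  seqs <- toupper(seqs)
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", seqs),
                      function(m) sum(m > 0), integer(1)))
  if (n_bad > 0) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    rf_log("WARN", n_bad, " non-ACGTN characters replaced by N in ", path)
  }
  seqs
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` is
#' replaced by `N` (counted and logged).  Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to a FASTA file, optionally gzipped.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- names(x)
  seqs <- as.character(x)
  tibble::tibble(id = unname(ids),
                 sequence = unname(clean_sequences(ids, seqs, path)))
}

#' Read reads from a FASTQ file
#'
#' Four-line FASTQ records; qualities are retained (the classifier does not
#' use them).  Gzip-compressed files are read transparently.
#'
#' @param path Path to a FASTQ file, optionally gzipped.
#' @return A tibble with columns `id`, `sequence` and `quality`.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      diagnose_fastq(path)
      stop("malformed FASTQ file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  ids <- names(x)
  seqs <- as.character(x)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad) > 0)
    stop("sequence/quality length mismatch for record '", ids[bad[1]], "'",
         call. = FALSE)
  tibble::tibble(id = unname(ids),
                 sequence = unname(clean_sequences(ids, seqs, path)),
                 quality = unname(qual))
}

# On parser failure, scan the 4-line records to name the offending one.
diagnose_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  i <- 0
  repeat {
    rec <- readLines(con, n = 4)
    if (length(rec) == 0) break
    i <- i + 1
    if (length(rec) < 4)
      stop("truncated FASTQ record #", i, " ('", rec[1], "') in ", path,
           call. = FALSE)
    if (nchar(rec[2]) != nchar(rec[4]))
      stop("sequence/quality length mismatch for record '",
           sub("^@", "", strsplit(rec[1], "\\s")[[1]][1]), "' in ", path,
           call. = FALSE)
  }
  invisible(NULL)
}

#' Write sequences to FASTA
#'
#' @param reads Tibble with columns `id`, `sequence`.
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::BStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path), width = 20000L)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with columns `id`, `sequence` and optionally `quality`
#'   (a constant high quality is written when absent).
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Strip a trailing /1, /2 (or whitespace-separated mate field) from read ids.
pair_key <- function(id) {
  id <- sub("\\s.*$", "", id)
  sub("/[12]$", "", id)
}

#' Interleave two mate streams of paired-end reads
#'
#' Reads are emitted in the order r1_1, r2_1, r1_2, r2_2, ...  Mate ids must
#' match up to a trailing `/1` / `/2` suffix (or whitespace-separated mate
#' field).
#'
#' @param r1,r2 Tibbles of mate-1 and mate-2 reads (columns `id`, `sequence`,
#'   optionally `quality`).
#' @return A single interleaved tibble with a `mate` column.
#' @export
interleave_pairs <- function(r1, r2) {
  if (nrow(r1) != nrow(r2))
    stop("mate streams differ in length: ", nrow(r1), " vs ", nrow(r2),
         call. = FALSE)
  if (nrow(r1) == 0) {
    out <- r1
    out$mate <- integer(0)
    return(out)
  }
  k1 <- pair_key(r1$id)
  k2 <- pair_key(r2$id)
  bad <- which(k1 != k2)
  if (length(bad) > 0)
    stop("mate id mismatch at position ", bad[1], ": '", r1$id[bad[1]],
         "' vs '", r2$id[bad[1]], "'", call. = FALSE)
  r1$mate <- 1L
  r2$mate <- 2L
  idx <- rep(seq_len(nrow(r1)), each = 2) +
    rep(c(0L, nrow(r1)), times = nrow(r1))
  dplyr::bind_rows(r1, r2)[idx, ]
}

#' Turn a tibble of records into a chunked stream
#'
#' A stream is a zero-argument function returning the next chunk (a tibble)
#' or `NULL` when exhausted; it underlies the bounded-memory batch contract.
#'
#' @param x A tibble of records.
#' @param chunk_size Rows per chunk.
#' @return A stream function.
#' @export
as_read_stream <- function(x, chunk_size = 1024L) {
  stopifnot(is.data.frame(x), chunk_size >= 1)
  pos <- 0L
  n <- nrow(x)
  function() {
    if (pos >= n) return(NULL)
    take <- min(chunk_size, n - pos)
    out <- x[(pos + 1L):(pos + take), , drop = FALSE]
    pos <<- pos + take
    out
  }
}

#' Stream a FASTA/FASTQ file in bounded-memory chunks
#'
#' @param path Sequence file path.
#' @param format `"fasta"` or `"fastq"`.
#' @param chunk_size Records per chunk.
#' @return A stream function (see [as_read_stream()]).
#' @export
seq_file_stream <- function(path, format = c("fasta", "fastq"),
                            chunk_size = 4096L) {
  format <- match.arg(format)
  skip <- 0L
  done <- FALSE
  function() {
    if (done) return(NULL)
    x <- if (format == "fasta") {
      Biostrings::readBStringSet(path, nrec = chunk_size, skip = skip)
    } else {
      Biostrings::readDNAStringSet(path, format = "fastq", nrec = chunk_size,
                                   skip = skip, with.qualities = TRUE)
    }
    if (length(x) == 0) { done <<- TRUE; return(NULL) }
    skip <<- skip + length(x)
    if (length(x) < chunk_size) done <<- TRUE
    out <- tibble::tibble(id = unname(names(x)),
                          sequence = unname(clean_sequences(names(x),
                                                            as.character(x),
                                                            path)))
    if (format == "fastq")
      out$quality <- unname(as.character(S4Vectors::mcols(x)$qualities))
    out
  }
}

#' Batch a record stream with an optional buffer shuffle
#'
#' Emits every record exactly once in batches of `batch_size`.  With
#' `shuffle_buffer = 0` the input order is preserved; otherwise records are
#' drawn uniformly from a rolling buffer of at most `shuffle_buffer` records,
#' so at no point are more than `shuffle_buffer + batch_size` records (plus
#' one reader chunk) held in memory.  When the buffer covers the whole input
#' this yields a uniformly random permutation.  A fixed `seed` gives an
#' identical batch sequence across runs.
#'
#' @param stream A stream function ([as_read_stream()], [seq_file_stream()])
#'   or a tibble (converted automatically).
#' @param batch_size Records per emitted batch (last batch may be smaller).
#' @param shuffle_buffer Buffer capacity in records; 0 disables shuffling.
#' @param seed Integer seed for the buffer draws.
#' @return A stream function emitting tibbles of at most `batch_size` rows.
#' @export
stream_batches <- function(stream, batch_size, shuffle_buffer = 0L,
                           seed = NULL) {
  stopifnot(batch_size >= 1, shuffle_buffer >= 0)
  if (is.data.frame(stream)) stream <- as_read_stream(stream)
  buf <- NULL          # rolling buffer (tibble), at most shuffle_buffer rows
  exhausted <- FALSE
  rng_state <- with_seed(seed %||% 0L, get(".Random.seed", globalenv()))

  draw <- function(n_avail, take) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", rng_state, envir = globalenv())
    i <- sample.int(n_avail, take)
    rng_state <<- get(".Random.seed", envir = globalenv())
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    i
  }

  refill <- function(target) {
    while (!exhausted && (is.null(buf) || nrow(buf) < target)) {
      chunk <- stream()
      if (is.null(chunk)) { exhausted <<- TRUE; break }
      buf <<- if (is.null(buf)) chunk else dplyr::bind_rows(buf, chunk)
    }
  }

  function() {
    got <- list()
    n_got <- 0L
    while (n_got < batch_size) {
      refill(max(shuffle_buffer, 1L))
      if (is.null(buf) || nrow(buf) == 0) break
      avail <- if (shuffle_buffer > 0) min(nrow(buf), shuffle_buffer)
               else nrow(buf)
      take <- min(batch_size - n_got, avail)
      idx <- if (shuffle_buffer > 0) draw(avail, take) else seq_len(take)
      got[[length(got) + 1L]] <- buf[idx, , drop = FALSE]
      buf <<- buf[-idx, , drop = FALSE]
      n_got <- n_got + take
    }
    if (n_got == 0L) return(NULL)
    dplyr::bind_rows(got)
  }
}

#' Collect all batches of a stream into one tibble
#'
#' @param stream A stream function.
#' @return A tibble of all emitted records, in emission order.
#' @export
stream_collect <- function(stream) {
  out <- list()
  repeat {
    b <- stream()
    if (is.null(b) || nrow(b) == 0) break
    out[[length(out) + 1L]] <- b
  }
  dplyr::bind_rows(out)
}
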