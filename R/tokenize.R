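# Tokenization: canonical k-mers, the combinatorial k-mer vocabulary, LSH
# bucketing and hash-embedding indices (both MurmurHash3-based), character
# tokens, and padding/batching with attention masks.
#
# Special ids are shared across schemes: PAD = 0, UNK = 1, CLS = 2; scheme
# ids start at 3.

PAD_ID <- 0L
UNK_ID <- 1L
CLS_ID <- 2L

#' Reverse complement of DNA sequences
#'
#' @param s Character vector over `{A,C,G,T,N}` (case preserved as upper).
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @export
revcomp <- function(s) {
  if (any(grepl("[^ACGTNacgtn]", s)))
    stop("revcomp: sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", s)
  vapply(comp, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Canonical form of k-mers
#'
#' The canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement, making tokenization strand-invariant.
#'
#' @param s Character vector of k-mers over `{A,C,G,T}`.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(s) {
  if (any(grepl("[^ACGT]", s)))
    stop("canonical_kmer: k-mers must be over {A,C,G,T}; windows containing ",
         "N are routed to UNK by encode_read()", call. = FALSE)
  rc <- revcomp(s)
  ifelse(s <= rc, s, rc)
}

#' Number of canonical k-mers
#'
#' Closed form: `4^k / 2` for odd k (no palindromes) and
#' `(4^k + 4^(k/2)) / 2` for even k.
#'
#' @param k k-mer length.
#' @return Integer count of canonical k-mers.
#' @export
n_canonical_kmers <- function(k) {
  if (k %% 2 == 1) 4^k / 2 else (4^k + 4^(k / 2)) / 2
}

#' Build the canonical k-mer vocabulary
#'
#' Enumerates all canonical k-mers combinatorially (no reference data
#' needed), assigning ids 3, 4, ... in lexicographic order after the special
#' ids PAD = 0, UNK = 1, CLS = 2.  A k-mer and its reverse complement share
#' one id.  The lookup table holds `4^k` integers, so memory grows steeply
#' with k (~256 MB at the practical cap k = 13).
#'
#' @param k k-mer length, 1 to 13.
#' @return An object of class `kmer_vocab` with fields `k`, `size`
#'   (3 + number of canonical k-mers) and the id lookup table.
#' @export
build_vocab <- function(k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  table <- cpp_vocab_table(as.integer(k))
  structure(list(k = as.integer(k),
                 size = 3L + attr(table, "n_canonical"),
                 table = table),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat("Canonical", x$k, "-mer vocabulary:", x$size - 3L,
      "k-mers (+3 special ids), size", x$size, "\n")
  invisible(x)
}

#' Look up vocabulary ids of k-mers
#'
#' @param vocab A `kmer_vocab`.
#' @param kmers Character vector of k-mers over `{A,C,G,T}`.
#' @return Integer ids in `[3, size)`; a k-mer and its reverse complement map
#'   to the same id.
#' @export
vocab_id <- function(vocab, kmers) {
  if (any(nchar(kmers) != vocab$k))
    stop("k-mer length mismatch: expected ", vocab$k, call. = FALSE)
  codes <- vapply(strsplit(kmers, "", fixed = TRUE), function(ch) {
    v <- match(ch, DNA_BASES) - 1L
    if (anyNA(v)) return(NA_real_)
    sum(v * 4^((length(v) - 1):0))
  }, numeric(1))
  if (anyNA(codes))
    stop("k-mers must be over {A,C,G,T}", call. = FALSE)
  vocab$table[codes + 1]
}

#' Stride-s k-mer tokens of a read
#'
#' @param read A single sequence string.
#' @param k k-mer length.
#' @param stride Offset between consecutive windows (default 1, overlapping).
#' @return Character vector of `floor((L - k) / stride) + 1` k-mers (empty if
#'   the read is shorter than k).
#' @export
kmer_tokens <- function(read, k, stride = 1L) {
  stopifnot(length(read) == 1, stride >= 1)
  L <- nchar(read)
  if (L < k) return(character(0))
  starts <- seq(1L, L - k + 1L, by = stride)
  substring(read, starts, starts + k - 1L)
}

#' Construct a tokenization scheme
#'
#' Bundles everything needed to turn reads into integer token streams under
#' one of four schemes:
#' \describe{
#'   \item{char}{one token per base (A,C,G,T,N -> 5 ids after the specials).}
#'   \item{vocab}{canonical k-mer vocabulary ids (see [build_vocab()]).}
#'   \item{lsh}{locality-sensitive k-mer bucketing: the canonical k-mer is
#'     subsampled at a fixed seeded subset of `ceiling(0.8 k)` positions and
#'     MurmurHash3-hashed into `b` buckets, so k-mers differing only at
#'     non-sampled positions collide.}
#'   \item{hash}{hash-embedding indices: `q` independent MurmurHash3 ids into
#'     a shared pool of `b` component vectors plus one importance-slot id
#'     into a table of size `W`.}
#' }
#'
#' @param scheme One of `"char"`, `"vocab"`, `"lsh"`, `"hash"`.
#' @param k k-mer length (ignored for `char`).
#' @param b Bucket count for `lsh` / `hash` (e.g. `2^22`).
#' @param q Number of hash component vectors per k-mer (`hash` only).
#' @param W Importance-table size (`hash` only; defaults to `b`).
#' @param seed Seed fixing the hash seeds and the LSH position subset.
#' @param n_max Maximum token-stream length; longer streams are truncated
#'   (logged).
#' @param with_cls Prepend a classification token by default.
#' @return An object of class `token_scheme`.
#' @export
token_scheme <- function(scheme = c("vocab", "char", "lsh", "hash"),
                         k = 12L, b = 2^22, q = 6L, W = NULL, seed = 1L,
                         n_max = 256L, with_cls = FALSE) {
  scheme <- match.arg(scheme)
  k <- as.integer(k)
  if (scheme %in% c("lsh", "hash") && b < 2)
    stop("bucket count b must be >= 2", call. = FALSE)
  W <- as.integer(W %||% b)
  obj <- list(scheme = scheme, k = k, b = as.integer(b), q = as.integer(q),
              W = W, seed = as.integer(seed), n_max = as.integer(n_max),
              with_cls = with_cls)
  # q + 1 distinct hash seeds: seeds[1] drives the importance slot (hash) or
  # the single LSH hash; seeds[2..q+1] drive the hash components.
  obj$seeds <- vapply(0:obj$q, function(j)
    derive_seed(seed, paste0("hash", j)), integer(1))
  if (scheme == "lsh") {
    m <- as.integer(ceiling(0.8 * k))
    obj$lsh_pos <- with_seed(derive_seed(seed, "lsh_pos"),
                             sort(sample.int(k, m)))
  }
  if (scheme == "vocab") {
    v <- build_vocab(k)
    obj$vocab <- v
  }
  obj$table_size <- switch(scheme,
    char = 8L,                 # PAD,UNK,CLS + A,C,G,T,N
    vocab = obj$vocab$size,
    lsh = as.integer(b + 3),
    hash = as.integer(b + 3))  # component pool rows (importance table: W + 3)
  structure(obj, class = "token_scheme")
}

#' @export
print.token_scheme <- function(x, ...) {
  cat("Token scheme '", x$scheme, "'", sep = "")
  if (x$scheme != "char") cat(", k =", x$k)
  if (x$scheme %in% c("lsh", "hash")) cat(", b =", x$b)
  if (x$scheme == "hash") cat(", q =", x$q, ", W =", x$W)
  cat(", table size", x$table_size, "\n")
  invisible(x)
}

#' LSH bucket of a k-mer
#'
#' Canonicalizes the k-mer, extracts the scheme's fixed random subset of
#' `ceiling(0.8 k)` positions, and MurmurHash3-hashes the subsequence modulo
#' `b`.  A k-mer and its reverse complement share a bucket, and k-mers
#' differing only at non-sampled positions collide (the locality property).
#'
#' @param kmer Character vector of k-mers of length `scheme$k`.
#' @param scheme A `token_scheme` with `scheme = "lsh"`.
#' @return Integer bucket ids in `[0, b)`.
#' @export
lsh_bucket <- function(kmer, scheme) {
  stopifnot(inherits(scheme, "token_scheme"), scheme$scheme == "lsh")
  if (any(nchar(kmer) != scheme$k))
    stop("k-mer length mismatch: expected ", scheme$k, call. = FALSE)
  can <- canonical_kmer(kmer)
  sub <- vapply(can, function(x)
    paste(strsplit(x, "", fixed = TRUE)[[1]][scheme$lsh_pos], collapse = ""),
    character(1), USE.NAMES = FALSE)
  cpp_murmur_mod(sub, scheme$seeds[1], scheme$b)
}

#' Hash-embedding indices of a k-mer
#'
#' Canonicalizes the k-mer, then derives `q` component ids (independent
#' MurmurHash3 seeds, modulo `b`) selecting vectors from the shared component
#' pool, plus one importance-slot id (modulo `W`) selecting the q importance
#' weights.
#'
#' @param kmer Character vector of k-mers of length `scheme$k`.
#' @param scheme A `token_scheme` with `scheme = "hash"`.
#' @return A list with `components` (matrix, one row per k-mer, q columns,
#'   values in `[0, b)`) and `importance` (vector, values in `[0, W)`).
#' @export
hash_indices <- function(kmer, scheme) {
  stopifnot(inherits(scheme, "token_scheme"), scheme$scheme == "hash")
  if (any(nchar(kmer) != scheme$k))
    stop("k-mer length mismatch: expected ", scheme$k, call. = FALSE)
  can <- canonical_kmer(kmer)
  comp <- vapply(seq_len(scheme$q), function(j)
    cpp_murmur_mod(can, scheme$seeds[j + 1], scheme$b), integer(length(can)))
  comp <- matrix(comp, nrow = length(can))
  list(components = comp,
       importance = cpp_murmur_mod(can, scheme$seeds[1], scheme$W))
}

#' Encode a read into an integer token stream
#'
#' K-mer windows containing `N` map to UNK; the char scheme keeps `N` as its
#' own token.  A classification token (id 2) is prepended when `with_cls`.
#' Streams longer than `scheme$n_max` are truncated (logged).
#'
#' @param read A single sequence string, optionally named with the read id.
#' @param scheme A `token_scheme`.
#' @param with_cls Override the scheme's `with_cls` default.
#' @return An object of class `token_stream`: fields `ids` (integer vector;
#'   for the hash scheme the importance-slot ids), `n`, `scheme`, `read_id`,
#'   and for the hash scheme `components` (n x q id matrix).  All ids are
#'   0-based with PAD = 0, UNK = 1, CLS = 2.
#' @export
encode_read <- function(read, scheme, with_cls = scheme$with_cls) {
  stopifnot(length(read) == 1)
  read_id <- names(read) %||% "read"
  enc <- encode_batch(unname(read), scheme, with_cls, ids = read_id)
  x <- enc[[1]]
  if (scheme$scheme == "hash") {
    structure(list(ids = x$imp, components = x$comp, n = length(x$imp),
                   scheme = scheme$scheme, read_id = read_id),
              class = "token_stream")
  } else {
    structure(list(ids = x, n = length(x), scheme = scheme$scheme,
                   read_id = read_id),
              class = "token_stream")
  }
}

# Bulk encoding used by training/inference; returns the raw C++ list.
encode_batch <- function(seqs, scheme, with_cls = scheme$with_cls,
                         ids = NULL) {
  out <- cpp_encode_reads(
    seqs, scheme$scheme, scheme$k,
    if (scheme$scheme == "vocab") scheme$vocab$table else integer(0),
    scheme$lsh_pos %||% integer(0),
    as.double(scheme$b), scheme$seeds, as.double(scheme$W), scheme$q,
    with_cls, scheme$n_max)
  lens <- vapply(out, function(x)
    if (is.list(x)) length(x$imp) else length(x), integer(1))
  if (any(lens == 0)) {
    bad <- which(lens == 0)[1]
    nm <- if (!is.null(ids)) ids[bad] else paste0("#", bad)
    stop("read '", nm, "' is shorter than k = ", scheme$k,
         "; no tokens produced", call. = FALSE)
  }
  if (attr(out, "truncated") > 0)
    rf_log("WARN", attr(out, "truncated"), " token streams truncated to n_max = ",
           scheme$n_max)
  out
}

#' Pad token streams into a batch with an attention mask
#'
#' @param streams A list of `token_stream` objects (or plain integer id
#'   vectors).  All must come from the same scheme.
#' @return An object of class `padded_batch`: `ids` (B x n_max matrix, PAD =
#'   0 beyond each stream), `mask` (logical matrix, `TRUE` = real token), and
#'   for hash streams `imp`/`comp` index arrays.
#' @export
pad_batch <- function(streams) {
  stopifnot(length(streams) >= 1)
  if (inherits(streams, "token_stream")) streams <- list(streams)
  get_ids <- function(s) if (inherits(s, "token_stream")) s$ids else s
  idl <- lapply(streams, get_ids)
  lens <- lengths(idl)
  n_max <- max(lens)
  B <- length(idl)
  ids <- matrix(PAD_ID, nrow = B, ncol = n_max)
  mask <- matrix(FALSE, nrow = B, ncol = n_max)
  for (i in seq_len(B)) {
    if (lens[i] > 0) {
      ids[i, seq_len(lens[i])] <- idl[[i]]
      mask[i, seq_len(lens[i])] <- TRUE
    }
  }
  out <- list(ids = ids, mask = mask, n_max = n_max, lengths = lens)
  first <- streams[[1]]
  if (inherits(first, "token_stream") && !is.null(first$components)) {
    q <- ncol(first$components)
    comp <- array(PAD_ID, dim = c(B, n_max, q))
    for (i in seq_len(B))
      if (lens[i] > 0) comp[i, seq_len(lens[i]), ] <- streams[[i]]$components
    out$imp <- ids
    out$comp <- comp
  }
  structure(out, class = "padded_batch")
}
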