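# Synthetic study system: taxonomy-structured genomes, coverage-balanced
# read sets with a parametric substitution error model, paired-end fragments
# with a Gaussian insert-size model, and log-normal mock communities.

DNA_BASES <- c("A", "C", "G", "T")

random_genome <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Substitute each base independently with total probability `rate`, choosing
# uniformly among the 3 alternative bases.
mutate_sequence <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) > 0) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- DNA_BASES[((match(ch[hit], DNA_BASES) - 1L + shift) %% 4L) + 1L]
    s <- paste(ch, collapse = "")
  }
  s
}

#' Simulate a two-level taxonomy of related genomes
#'
#' One random ancestor genome is drawn per genus (all genera descend from a
#' shared root mutated at rate `d_between`); each species genome is its genus
#' ancestor with independent per-site substitutions at rate `d_within`.
#' Within-genus divergence must be smaller than between-genus divergence,
#' otherwise genus membership carries no signal.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @param genome_length Genome length in bp (>= 1000).
#' @param d_between Per-site substitution rate from the root to each genus
#'   ancestor.
#' @param d_within Per-site substitution rate from a genus ancestor to each
#'   of its species.
#' @param seed Integer seed; results are bit-reproducible.
#' @return An object of class `sim_taxonomy`: a list with `genomes` (tibble
#'   `species_id`, `genus_id`, `sequence`, `length`) and the simulation
#'   parameters.
#' @export
simulate_taxonomy <- function(n_genera, species_per_genus, genome_length,
                              d_between, d_within, seed) {
  if (d_within < 0 || d_between > 0.5)
    stop("require 0 <= d_within < d_between <= 0.5", call. = FALSE)
  if (d_within >= d_between)
    stop("d_within must be smaller than d_between ",
         "(genus classes would be unlearnable)", call. = FALSE)
  if (genome_length < 1000) stop("genome_length must be >= 1 kb", call. = FALSE)
  with_seed(seed, {
    root <- random_genome(genome_length)
    rows <- list()
    for (g in seq_len(n_genera)) {
      anc <- mutate_sequence(root, d_between)
      for (s in seq_len(species_per_genus)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species_id = sprintf("g%d_s%d", g, s),
          genus_id = sprintf("g%d", g),
          sequence = mutate_sequence(anc, d_within))
      }
    }
    genomes <- dplyr::bind_rows(rows)
    genomes$length <- nchar(genomes$sequence)
    structure(list(genomes = genomes, n_genera = n_genera,
                   species_per_genus = species_per_genus,
                   d_between = d_between, d_within = d_within, seed = seed),
              class = "sim_taxonomy")
  })
}

#' @export
print.sim_taxonomy <- function(x, ...) {
  cat("Simulated taxonomy:", x$n_genera, "genera x", x$species_per_genus,
      "species,", x$genomes$length[1], "bp genomes\n")
  cat("  divergence: between-genus", x$d_between, "/ within-genus",
      x$d_within, "\n")
  invisible(x)
}

#' Coverage-balanced per-genome sequencing effort
#'
#' To balance classes of unequal genome length, each genome is sequenced at
#' coverage `round(L_max / L_i) * f` (nearest integer, ties to even), so the
#' per-class base totals agree up to rounding.
#'
#' @param lengths Positive genome lengths in bp (optionally named).
#' @param f Coverage factor (integer >= 1); the reference choice is 3 for
#'   training sets and 1 for validation sets.
#' @return A tibble with columns `genome` (names or index), `length`,
#'   `coverage`, carrying `f` as an attribute.
#' @export
balanced_coverages <- function(lengths, f) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (f < 1 || f != as.integer(f))
    stop("coverage factor f must be an integer >= 1", call. = FALSE)
  cov <- as.integer(round(max(lengths) / lengths) * f)
  out <- tibble::tibble(
    genome = if (is.null(names(lengths))) as.character(seq_along(lengths))
             else names(lengths),
    length = as.integer(lengths),
    coverage = cov)
  attr(out, "f") <- as.integer(f)
  out
}

#' Simulate sequencing reads from one genome
#'
#' Fragments start uniformly on the genome; for paired-end data the insert
#' length is drawn from Normal(`insert_mu`, `insert_sd`) and clamped to
#' `[read_len, genome length]`, mate 1 is the fragment start and mate 2 the
#' reverse complement of the fragment end.  Sequencing errors are independent
#' per-base substitutions at rate `err_rate` (uniform over the 3 alternative
#' bases).  The number of fragments is
#' `round(coverage * L / (reads_per_fragment * read_len))`.
#'
#' @param genome A single sequence string, or a one-row tibble/list with
#'   `sequence` plus optional `species_id`/`genus_id` labels carried into the
#'   output as ground truth.
#' @param coverage Target mean coverage (> 0).
#' @param read_len Read length in bp (default 150).
#' @param paired Generate read pairs?
#' @param insert_mu,insert_sd Insert-size model in bp (defaults 400 and 50).
#' @param err_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param id_prefix Prefix namespacing the read ids.
#' @return A tibble of reads: `id`, `sequence`, `mate`, `fragment`, plus any
#'   truth label columns from `genome`.
#' @export
simulate_reads <- function(genome, coverage, read_len = 150L, paired = TRUE,
                           insert_mu = 400, insert_sd = 50, err_rate = 0,
                           seed = 1L, id_prefix = "") {
  if (is.character(genome)) genome <- list(sequence = genome, species_id = "s1")
  gseq <- genome$sequence[[1]]
  L <- nchar(gseq)
  gid <- genome$species_id[[1]] %||% "genome"
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  if (read_len > L) stop("read_len exceeds genome length", call. = FALSE)
  rpf <- if (paired) 2L else 1L
  n_frag <- round(coverage * L / (rpf * read_len))
  with_seed(seed, {
    if (paired) {
      ins <- pmin(pmax(round(rnorm(n_frag, insert_mu, insert_sd)), read_len), L)
      start <- floor(runif(n_frag) * (L - ins + 1)) + 1L
      m1 <- substring(gseq, start, start + read_len - 1L)
      end <- start + ins - 1L
      m2 <- revcomp(substring(gseq, end - read_len + 1L, end))
      reads <- tibble::tibble(
        id = sprintf("%s%s:f%d/%d", id_prefix, gid,
                     rep(seq_len(n_frag), each = 2L), rep(1:2, n_frag)),
        sequence = as.vector(rbind(m1, m2)),
        mate = rep(1:2, n_frag),
        fragment = rep(seq_len(n_frag), each = 2L),
        insert = rep(ins, each = 2L))
    } else {
      start <- floor(runif(n_frag) * (L - read_len + 1)) + 1L
      reads <- tibble::tibble(
        id = sprintf("%s%s:f%d", id_prefix, gid, seq_len(n_frag)),
        sequence = substring(gseq, start, start + read_len - 1L),
        mate = NA_integer_,
        fragment = seq_len(n_frag),
        insert = NA_real_)
    }
    if (err_rate > 0)
      reads$sequence <- vapply(reads$sequence, mutate_sequence, character(1),
                               rate = err_rate, USE.NAMES = FALSE)
    if (!is.null(genome$species_id)) reads$species_id <- genome$species_id[[1]]
    if (!is.null(genome$genus_id)) reads$genus_id <- genome$genus_id[[1]]
    reads
  })
}

#' Generate a coverage-balanced labelled read set from a taxonomy
#'
#' Applies [balanced_coverages()] to the genome lengths, simulates reads per
#' genome with [simulate_reads()], and shuffles the pooled reads (so training
#' batches mix classes).  Read ids are namespaced by `id_prefix`, keeping
#' train/validation sets disjoint.
#'
#' @param taxonomy A `sim_taxonomy` object.
#' @param f Coverage factor (see [balanced_coverages()]).
#' @param read_len,paired,insert_mu,insert_sd,err_rate Read model, as in
#'   [simulate_reads()].
#' @param seed Integer seed.
#' @param id_prefix Read id namespace prefix.
#' @return A tibble of labelled reads (`id`, `sequence`, `mate`,
#'   `species_id`, `genus_id`).
#' @export
generate_balanced_set <- function(taxonomy, f, read_len = 150L, paired = TRUE,
                                  insert_mu = 400, insert_sd = 50,
                                  err_rate = 0, seed = 1L, id_prefix = "") {
  genomes <- taxonomy$genomes
  if (nrow(genomes) < 2) stop("taxonomy must have >= 2 classes", call. = FALSE)
  cov <- balanced_coverages(setNames(genomes$length, genomes$species_id), f)
  reads <- purrr::map2(seq_len(nrow(genomes)), cov$coverage, function(i, ci) {
    simulate_reads(genomes[i, ], coverage = ci, read_len = read_len,
                   paired = paired, insert_mu = insert_mu,
                   insert_sd = insert_sd, err_rate = err_rate,
                   seed = derive_seed(seed, paste0("reads:", i)),
                   id_prefix = id_prefix)
  })
  reads <- dplyr::bind_rows(reads)
  perm <- with_seed(derive_seed(seed, "shuffle"),
                    sample.int(nrow(reads)))
  reads <- reads[perm, ]
  reads[, c("id", "sequence", "mate", "species_id", "genus_id")]
}

#' Integer read counts for a community from relative abundances
#'
#' Converts abundances `A_i` into counts `R_i = A_i / sum(A) * M` with
#' largest-remainder rounding, so the counts always sum to `M` exactly and
#' each count is within one read of its exact share.  Remainder ties are
#' broken by index order.
#'
#' @param abundances Positive abundances.
#' @param M Total read count (>= 0).
#' @return Integer vector of counts summing to `M`.
#' @export
mock_counts <- function(abundances, M) {
  if (any(abundances < 0) || sum(abundances) == 0)
    stop("abundances must be positive", call. = FALSE)
  if (M < 0) stop("M must be non-negative", call. = FALSE)
  share <- abundances / sum(abundances) * M
  base <- floor(share)
  need <- round(M - sum(base))
  if (need > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Draw a log-normal mock community
#'
#' Member abundances are `exp(Normal(mu, sigma))` (the reference parameters
#' are mu = 1, sigma = 2) and are scaled to a fixed total read count via
#' [mock_counts()], so `sum(count) == M` exactly.
#'
#' @param members Character vector of class ids.
#' @param mu,sigma Log-scale mean and sd of the abundance distribution.
#' @param M Total read count of the community.
#' @param seed Integer seed.
#' @param abundances Optional fixed abundances overriding the log-normal draw
#'   (for controlled experiments).
#' @return A `community_profile` tibble: `class_id`, `abundance`, `count`.
#' @export
sample_lognormal_community <- function(members, mu = 1, sigma = 2, M,
                                       seed = 1L, abundances = NULL) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (is.null(abundances))
    abundances <- with_seed(seed, exp(rnorm(length(members), mu, sigma)))
  stopifnot(length(abundances) == length(members))
  out <- tibble::tibble(class_id = members, abundance = abundances,
                        count = mock_counts(abundances, M))
  class(out) <- c("community_profile", class(out))
  out
}
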