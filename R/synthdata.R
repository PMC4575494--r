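# Deterministic synthetic-data generation: frequency tables, reference
# profiles, and simulated evidence under known drop-out/drop-in, so every
# module and property test runs without any external download. All
# randomness is confined by withr::with_seed, leaving the caller's RNG
# state untouched.

#' Generate a synthetic allele-frequency table
#'
#' Per-locus frequencies are normalized gamma draws (shape 1.5, giving the
#' uneven allele spectra typical of STR loci), summing to 1 per marker.
#' Defaults emulate a standard autosomal STR panel: 13 markers, 8 alleles
#' each (labelled by repeat count from 8 upward), and a database of 1036
#' individuals, the size of the commonly used US population dataset.
#'
#' @param seed Integer seed; the same seed reproduces the same table.
#' @param markers Number of markers.
#' @param alleles_per_marker Number of alleles per marker.
#' @param n_individuals Database size behind the frequencies.
#' @param population Population label.
#' @return A [frequency_table()].
#' @export
make_frequency_table <- function(seed, markers = 13L, alleles_per_marker = 8L,
                                 n_individuals = 1036L,
                                 population = "synthetic") {
  markers <- as.integer(markers)
  alleles_per_marker <- as.integer(alleles_per_marker)
  if (markers < 1 || alleles_per_marker < 1)
    stop("markers and alleles_per_marker must be >= 1")
  labels <- as.character(seq(8L, length.out = alleles_per_marker))
  freqs <- withr::with_seed(seed, {
    lapply(seq_len(markers), function(i) {
      x <- stats::rgamma(alleles_per_marker, shape = 1.5)
      stats::setNames(x / sum(x), labels)
    })
  })
  names(freqs) <- sprintf("M%02d", seq_len(markers))
  frequency_table(population, n_individuals, freqs)
}

#' Draw a random genotype from a frequency table
#'
#' Two independent allele draws from the locus frequencies (a theta = 0
#' population). Uses the current RNG stream unless `seed` is given.
#'
#' @param table A [frequency_table()].
#' @param marker Marker name.
#' @param seed Optional seed for reproducibility.
#' @return A [genotype()].
#' @export
sample_genotype <- function(table, marker, seed = NULL) {
  f <- table$freqs[[marker]]
  if (is.null(f)) stop("marker ", marker, " not in table")
  draw <- function() {
    a <- sample(names(f), 2L, replace = TRUE, prob = f)
    genotype(a[1], a[2])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Draw a full random reference profile
#'
#' @param table A [frequency_table()].
#' @param sample_name Name to attach.
#' @param seed Optional seed.
#' @return A [reference_profile()] typed at every marker of `table`.
#' @export
sample_reference_profile <- function(table, sample_name, seed = NULL) {
  draw <- function() {
    gts <- lapply(names(table$freqs), function(m) sample_genotype(table, m))
    names(gts) <- names(table$freqs)
    reference_profile(sample_name, gts)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate an evidence profile from known contributors
#'
#' Each allele *copy* of each contributor drops out independently with
#' probability `p_do` (so per-allele survival matches the engine's factors
#' exactly when `alpha = 1`); with probability `p_di` exactly one drop-in
#' allele, drawn by population frequency, is added. Detected alleles are
#' returned as a set.
#'
#' @param contributors List of [reference_profile()] objects, each typed at
#'   every marker of `table`.
#' @param p_do Per-copy drop-out probability.
#' @param p_di Per-locus drop-in probability.
#' @param table A [frequency_table()] supplying the markers and the drop-in
#'   allele distribution.
#' @param seed Optional seed.
#' @return Named list (marker -> [locus_evidence()]).
#' @export
simulate_evidence <- function(contributors, p_do, p_di, table, seed = NULL) {
  stopifnot(is_probability(p_do), is_probability(p_di))
  run <- function() {
    out <- list()
    for (m in names(table$freqs)) {
      copies <- unlist(lapply(contributors, function(p) {
        g <- p$genotypes[[m]]
        if (is.null(g)) stop("contributor '", p$sample_name,
                             "' not typed at ", m)
        g
      }), use.names = FALSE)
      survived <- copies[stats::runif(length(copies)) >= p_do]
      det <- unique(survived)
      if (stats::runif(1) < p_di) {
        f <- table$freqs[[m]]
        det <- unique(c(det, sample(names(f), 1L, prob = f)))
      }
      out[[m]] <- locus_evidence(m, det)
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
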