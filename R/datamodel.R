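# Domain types: genotypes, evidence, reference profiles, frequency tables,
# parameters, hypotheses. All are light S3 lists with validating constructors;
# alleles are opaque string labels ("12", "13.3", "OL") compared by exact
# string equality after whitespace trimming -- never interpreted numerically.

#' Construct an unordered genotype
#'
#' A genotype is a canonically ordered pair of allele labels, so that
#' `genotype("14", "15")` and `genotype("15", "14")` compare equal with
#' [identical()]. A homozygote repeats the same label.
#'
#' @param a1,a2 Allele labels (non-empty strings; whitespace is trimmed).
#' @return Character vector of length 2, sorted.
#' @examples
#' identical(genotype("15", "14"), genotype("14", "15"))
#' @export
genotype <- function(a1, a2 = a1) {
  a1 <- trimws(as.character(a1))
  a2 <- trimws(as.character(a2))
  if (length(a1) != 1 || length(a2) != 1 || !nzchar(a1) || !nzchar(a2))
    stop("allele labels must be single non-empty strings")
  if (a1 <= a2) c(a1, a2) else c(a2, a1)
}

#' Evidence alleles detected at one locus
#'
#' @param marker Marker (locus) name.
#' @param detected Character vector of detected allele labels; duplicates are
#'   collapsed (set semantics). May be empty: an evidence row with no alleles
#'   is treated as complete locus drop-out, not as missing data.
#' @param heights Optional named numeric vector of peak heights (RFU), names
#'   a subset of `detected`, all positive.
#' @return Object of class `locus_evidence`.
#' @export
locus_evidence <- function(marker, detected = character(), heights = NULL) {
  marker <- trimws(as.character(marker))
  if (length(marker) != 1 || !nzchar(marker)) stop("marker must be a non-empty string")
  detected <- unique(trimws(as.character(detected)))
  detected <- detected[nzchar(detected)]
  if (!is.null(heights)) {
    if (!is.numeric(heights) || is.null(names(heights)))
      stop("heights must be a named numeric vector")
    if (!all(names(heights) %in% detected))
      stop("heights keys must be a subset of detected alleles at ", marker)
    if (any(heights <= 0)) stop("peak heights must be positive")
  }
  structure(list(marker = marker, detected = detected, heights = heights),
            class = "locus_evidence")
}

#' Reference profile of a typed individual
#'
#' @param sample_name Sample name.
#' @param genotypes Named list mapping marker to [genotype()].
#' @return Object of class `reference_profile`.
#' @export
reference_profile <- function(sample_name, genotypes) {
  if (!is.list(genotypes) || (length(genotypes) > 0 && is.null(names(genotypes))))
    stop("genotypes must be a named list of genotype() pairs")
  if (anyDuplicated(names(genotypes)))
    stop("each marker may appear at most once in a reference profile")
  genotypes <- lapply(genotypes, function(g) genotype(g[1], g[2]))
  structure(list(sample_name = as.character(sample_name), genotypes = genotypes),
            class = "reference_profile")
}

#' Population allele-frequency table
#'
#' @param population Population label.
#' @param n_individuals Number of individuals in the frequency database
#'   (`n` in the 5/2n minimum-frequency rule).
#' @param freqs Named list mapping marker to a named numeric vector of allele
#'   frequencies, each in (0, 1]. Per-locus sums may not exceed 1 by more
#'   than 1e-6 at construction; after [apply_min_frequency()] the sum may
#'   exceed 1 (no renormalization is ever applied).
#' @return Object of class `frequency_table`.
#' @export
frequency_table <- function(population, n_individuals, freqs) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1)
    stop("n_individuals must be a positive integer")
  if (!is.list(freqs) || (length(freqs) > 0 && is.null(names(freqs))))
    stop("freqs must be a named list (marker -> named numeric vector)")
  for (m in names(freqs)) {
    f <- freqs[[m]]
    if (!is.numeric(f) || is.null(names(f)))
      stop("frequencies at ", m, " must be a named numeric vector")
    if (any(f <= 0) || any(f > 1))
      stop("frequencies at ", m, " must lie in (0, 1]")
    if (anyDuplicated(names(f))) stop("duplicate allele at ", m)
  }
  structure(list(population = as.character(population),
                 n_individuals = n_individuals,
                 freqs = freqs,
                 floored = FALSE),
            class = "frequency_table")
}

#' Model parameters
#'
#' Defaults mirror common forensic practice: drop-in probability 0.01,
#' coancestry coefficient theta (F_ST) 0.01, and homozygote drop-out
#' correction alpha = 0.5 (complete drop-out of c copies of an allele has
#' probability alpha^(c-1) * p_dropout^c).
#'
#' @param p_dropout Per-allele drop-out probability P(D_O), in \[0, 1).
#' @param p_dropin Probability that exactly one allele drops in at a locus,
#'   in \[0, 1).
#' @param theta Coancestry coefficient, in \[0, 1).
#' @param alpha Multi-copy drop-out correction, in (0, 1\].
#' @return Object of class `lr_params`.
#' @export
lr_params <- function(p_dropout, p_dropin = 0.01, theta = 0.01, alpha = 0.5) {
  chk <- function(x, nm, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x))
      stop(nm, " must be a single number")
    ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
    if (!ok) stop(nm, " = ", x, " out of range")
  }
  chk(p_dropout, "p_dropout", 0, 1, hi_open = TRUE)
  chk(p_dropin, "p_dropin", 0, 1, hi_open = TRUE)
  chk(theta, "theta", 0, 1, hi_open = TRUE)
  chk(alpha, "alpha", 0, 1, lo_open = TRUE)
  structure(list(p_dropout = p_dropout, p_dropin = p_dropin,
                 theta = theta, alpha = alpha),
            class = "lr_params")
}

#' Identity-by-descent probabilities for a relative
#'
#' `k0`, `k1`, `k2` are the probabilities that a relative shares 0, 1 or 2
#' alleles identical by descent with the suspected contributor; they must sum
#' to 1. Standard values: full siblings (1/4, 1/2, 1/4), parent-child
#' (0, 1, 0), unrelated (1, 0, 0), identical twins (0, 0, 1).
#'
#' @param k0,k1,k2 Probabilities summing to 1 (tolerance 1e-9).
#' @return Object of class `ibd_triple`.
#' @export
ibd_triple <- function(k0, k1, k2) {
  for (k in list(k0, k1, k2))
    if (!is_probability(k)) stop("IBD probabilities must lie in [0, 1]")
  if (abs(k0 + k1 + k2 - 1) > 1e-9)
    stop("IBD probabilities must sum to 1 (got ", k0 + k1 + k2, ")")
  structure(list(k0 = k0, k1 = k1, k2 = k2), class = "ibd_triple")
}

#' One side of a likelihood-ratio hypothesis
#'
#' @param includes_suspect Does this side name the suspected contributor as a
#'   true contributor?
#' @param n_unknowns Number of unknown contributors, at most 4 (at most 3 when
#'   the suspect is also named on this side).
#' @param relative Optional [ibd_triple()]: one of the unknowns is a random
#'   relative of the suspected contributor rather than an unrelated
#'   individual. Only valid on a side that does not itself include the
#'   suspect, and consumes one of `n_unknowns` (so requires
#'   `n_unknowns >= 1`).
#' @return Object of class `hypothesis`.
#' @export
hypothesis <- function(includes_suspect, n_unknowns = 0L, relative = NULL) {
  if (!is.logical(includes_suspect) || length(includes_suspect) != 1 ||
      is.na(includes_suspect))
    stop("includes_suspect must be TRUE or FALSE")
  n_unknowns <- as.integer(n_unknowns)
  if (is.na(n_unknowns) || n_unknowns < 0)
    stop("n_unknowns must be a non-negative integer")
  if (n_unknowns > 4)
    stop("at most 4 unknown contributors are supported (got ", n_unknowns, ")")
  if (includes_suspect && n_unknowns > 3)
    stop("with a named suspected contributor at most 3 unknowns are supported")
  if (!is.null(relative)) {
    if (!inherits(relative, "ibd_triple"))
      stop("relative must be an ibd_triple()")
    if (includes_suspect)
      stop("a relative hypothesis is only valid on a side without the suspect")
    if (n_unknowns < 1)
      stop("the relative consumes one unknown contributor; n_unknowns must be >= 1")
  }
  structure(list(includes_suspect = includes_suspect,
                 n_unknowns = n_unknowns, relative = relative),
            class = "hypothesis")
}

#' Numerator/denominator hypothesis pair
#'
#' Assumed (undisputed) contributors are shared by both sides: their detected
#' alleles mask matching evidence peaks on the numerator and denominator
#' alike, and they are not counted among the hypothesized unknown or
#' suspected contributors.
#'
#' @param numerator,denominator [hypothesis()] objects.
#' @param assumed List of [reference_profile()] objects for assumed
#'   contributors (common to both sides).
#' @return Object of class `hypothesis_pair`.
#' @export
hypothesis_pair <- function(numerator, denominator, assumed = list()) {
  if (!inherits(numerator, "hypothesis") || !inherits(denominator, "hypothesis"))
    stop("numerator and denominator must be hypothesis() objects")
  if (!is.list(assumed) || !all(vapply(assumed, inherits, logical(1), "reference_profile")))
    stop("assumed must be a list of reference_profile() objects")
  structure(list(numerator = numerator, denominator = denominator,
                 assumed = assumed),
            class = "hypothesis_pair")
}

#' Validate a case before computation
#'
#' Checks that every evidence marker can be resolved against every frequency
#' table, that the suspect is typed wherever a hypothesis needs them, and that
#' hypothesis limits hold. Assumed-contributor alleles absent from the
#' evidence at their locus yield a warning only: an undetected peak cannot
#' mask anything, so the allele is simply excluded from the masking set.
#'
#' @param evidence Named list (marker -> [locus_evidence()]).
#' @param suspect [reference_profile()] of the suspected contributor, or
#'   `NULL` when no side names a suspect.
#' @param hyp [hypothesis_pair()].
#' @param tables List of [frequency_table()] objects.
#' @return Object of class `validation_report`: a list with `issues` (a
#'   data.frame with columns `level`, `marker`, `message`) and `ok` (TRUE when
#'   no fatal issue was found).
#' @export
validate_case <- function(evidence, suspect, hyp, tables) {
  issues <- list()
  note <- function(level, marker, message)
    issues[[length(issues) + 1L]] <<- data.frame(level = level, marker = marker,
                                                 message = message)
  if (!inherits(hyp, "hypothesis_pair"))
    stop("hyp must be a hypothesis_pair()")
  if (inherits(tables, "frequency_table")) tables <- list(tables)
  if (length(tables) == 0) note("fatal", NA, "no frequency tables supplied")
  if (length(evidence) == 0 || is.null(names(evidence)))
    stop("evidence must be a named list of locus_evidence objects")

  needs_suspect <- hyp$numerator$includes_suspect ||
    hyp$denominator$includes_suspect ||
    !is.null(hyp$numerator$relative) || !is.null(hyp$denominator$relative)
  markers <- names(evidence)
  for (m in markers) {
    for (tab in tables) {
      if (is.null(tab$freqs[[m]]))
        note("fatal", m, sprintf("marker %s missing from frequency table '%s'",
                                 m, tab$population))
    }
    if (needs_suspect && (is.null(suspect) || is.null(suspect$genotypes[[m]])))
      note("fatal", m, sprintf("suspect genotype required but missing at %s", m))
    det <- evidence[[m]]$detected
    if (length(det) == 0)
      note("info", m, "no detected alleles; analyzed as complete locus drop-out")
    for (ap in hyp$assumed) {
      g <- ap$genotypes[[m]]
      if (is.null(g)) next
      missing_alleles <- setdiff(unique(g), det)
      if (length(missing_alleles) > 0)
        note("warning", m,
             sprintf("assumed contributor '%s' allele(s) %s not detected; excluded from masking",
                     ap$sample_name, paste(missing_alleles, collapse = ",")))
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(level = character(), marker = character(), message = character())
  structure(list(issues = issues, ok = !any(issues$level == "fatal")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$ok) "Case validation: OK" else "Case validation: FATAL ISSUES", "\n")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s: %s\n", x$issues$level[i],
                  x$issues$marker[i], x$issues$message[i]))
  }
  invisible(x)
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("Likelihood ratios, population '%s'\n", x$population))
  for (m in names(x$per_locus))
    cat(sprintf("  %-12s %s\n", m, format(x$per_locus[[m]], digits = 6)))
  cat(sprintf("  %-12s %s\n", "Overall", format(x$overall, digits = 6)))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
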