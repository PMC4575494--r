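# Core semi-continuous likelihood engine.
#
# Per-locus evidence probabilities under drop-out/drop-in, summation over the
# genotypes of unknown contributors (dynamic programming over allele-count
# vectors, with exhaustive enumeration retained as an independent oracle),
# and LR assembly across loci and populations.

#' Probability that all copies of an allele drop out
#'
#' For `copies` copies of an allele among the hypothesized contributors, the
#' probability that the allele is not detected is
#' `alpha^(copies - 1) * p_do^copies`; with `alpha = 0.5` a homozygote drops
#' out with probability `0.5 * p_do^2`, somewhat less than independence would
#' give.
#'
#' @param copies Number of copies carried (integer >= 1).
#' @param p_do Per-allele drop-out probability.
#' @param alpha Multi-copy correction in (0, 1].
#' @return Drop-out probability; detection probability is 1 minus this.
#' @export
dropout_prob <- function(copies, p_do, alpha) {
  if (length(copies) != 1 || is.na(copies) || copies < 1)
    stop("copies must be a positive integer")
  alpha^(copies - 1) * p_do^copies
}

#' Probability of an evidence profile given fixed contributor alleles
#'
#' Multiplies, over alleles, the drop-out or detection factor implied by the
#' contributor allele counts, treats alleles masked by an assumed contributor
#' as certainly detected (factor 1, regardless of how many other contributors
#' carry them), and closes with the drop-in term: no unexplained evidence
#' allele costs `(1 - p_dropin)`, exactly one unexplained allele `d` costs
#' `p_dropin * p_d` (floored frequency), and two or more unexplained alleles
#' are impossible under the at-most-one-drop-in model (probability 0).
#'
#' @param detected Character vector of detected evidence alleles (or a
#'   [locus_evidence()] object).
#' @param cc Contributor allele counts: named numeric vector or character
#'   vector of allele labels with multiplicity (2 per contributor).
#' @param mask Character vector of assumed-contributor alleles detected in the
#'   evidence (must be a subset of `detected`).
#' @param params [lr_params()].
#' @param locus_freqs Named numeric vector of floored allele frequencies.
#' @return Probability of observing exactly `detected` at this locus.
#' @export
locus_evidence_prob <- function(detected, cc = NULL, mask = character(),
                                params, locus_freqs) {
  if (inherits(detected, "locus_evidence")) detected <- detected$detected
  cc <- as_counts(cc)
  if (!all(mask %in% detected))
    stop("masking alleles must be a subset of the detected evidence alleles")
  prob <- 1
  for (i in seq_along(cc)) {
    a <- names(cc)[i]
    if (a %in% mask) next
    d <- dropout_prob(cc[[i]], params$p_dropout, params$alpha)
    prob <- prob * (if (a %in% detected) 1 - d else d)
  }
  unexplained <- setdiff(detected, c(names(cc), mask))
  if (length(unexplained) == 0) {
    prob * (1 - params$p_dropin)
  } else if (length(unexplained) == 1) {
    i <- match(unexplained, names(locus_freqs))
    if (is.na(i))
      stop("drop-in allele '", unexplained, "' has no frequency")
    prob * params$p_dropin * locus_freqs[[i]]
  } else {
    0
  }
}

# Sequential sampling weight for assigning c copies of one allele to the
# unknowns, divided by c! (the multinomial factor (2U)! is applied globally):
#   prod_{j=0}^{c-1} ((m0 + j) * theta + (1 - theta) * p) / c!
# The shared denominator prod_t (1 + (T0 + t - 1) * theta) is also global
# because it depends only on the draw index, not on which allele is drawn --
# this exchangeability is what makes the count-vector DP exact.
sampling_weight <- function(c, m0, p, theta) {
  if (c == 0) return(1)
  w <- 1
  for (j in 0:(c - 1)) w <- w * ((m0 + j) * theta + (1 - theta) * p)
  w / factorial(c)
}

# DP core: sum over all unordered genotype assignments to n_unknown unrelated
# unknowns of [sequential conditional genotype-set probability x evidence
# probability]. The evidence factor depends on the unknowns only through the
# allele-count vector, so we convolve over the allele universe with state
# (copies assigned so far, number of unexplained evidence alleles so far),
# folding the drop-in frequency weight in when an evidence allele ends up
# with zero contributor copies.
dp_unknowns <- function(detected, fixed, mask, n_unknown, base_cond, params,
                        locus_freqs) {
  if (n_unknown == 0)
    return(locus_evidence_prob(detected, fixed, mask, params, locus_freqs))
  alleles <- names(locus_freqs)
  if (length(alleles) == 0) stop("empty allele universe at this locus")
  missing_e <- setdiff(detected, alleles)
  if (length(missing_e))
    stop("evidence allele(s) without frequency: ",
         paste(missing_e, collapse = ","), " (apply the 5/2n floor first)")
  if (length(setdiff(names(fixed), alleles)))
    stop("fixed contributor allele(s) without frequency")
  U2 <- 2L * n_unknown
  theta <- params$theta
  p_do <- params$p_dropout
  alpha <- params$alpha
  T0 <- sum(base_cond)

  dp0 <- c(1, numeric(U2))  # no unexplained evidence allele yet
  dp1 <- numeric(U2 + 1)    # exactly one (drop-in frequency already folded in)
  for (a in alleles) {
    i <- match(a, names(base_cond)); m0 <- if (is.na(i)) 0 else base_cond[[i]]
    i <- match(a, names(fixed));     fx <- if (is.na(i)) 0 else fixed[[i]]
    p <- locus_freqs[[a]]
    in_e <- a %in% detected
    in_m <- a %in% mask
    # per-copy-count weight: sampling weight x evidence factor
    w <- numeric(U2 + 1)
    for (cps in 0:U2) {
      t <- fx + cps
      ev <- if (in_m) 1
      else if (t >= 1) {
        d <- alpha^(t - 1) * p_do^t
        if (in_e) 1 - d else d
      } else 1  # t == 0: absent allele, or unexplained (handled below)
      w[cps + 1] <- sampling_weight(cps, m0, p, theta) * ev
    }
    unexplained_capable <- in_e && !in_m && fx == 0
    new0 <- numeric(U2 + 1)
    new1 <- numeric(U2 + 1)
    for (k in 0:U2) {
      v0 <- dp0[k + 1]; v1 <- dp1[k + 1]
      if (v0 == 0 && v1 == 0) next
      for (cps in 0:(U2 - k)) {
        wt <- w[cps + 1]
        if (wt == 0) next
        idx <- k + cps + 1
        if (unexplained_capable && cps == 0) {
          # this evidence allele gets no contributor copy: it becomes the
          # (at most one) drop-in allele; a second such allele kills the path
          new1[idx] <- new1[idx] + v0 * wt * p
        } else {
          new0[idx] <- new0[idx] + v0 * wt
          new1[idx] <- new1[idx] + v1 * wt
        }
      }
    }
    dp0 <- new0
    dp1 <- new1
  }
  # draw t (1-indexed) conditions on T0 + t - 1 already-sampled copies, so
  # its Balding-Nichols denominator is 1 + (T0 + t - 2) * theta
  denom <- if (U2 > 0) prod(1 + (T0 - 1 + 0:(U2 - 1)) * theta) else 1
  factorial(U2) *
    (dp0[U2 + 1] * (1 - params$p_dropin) + dp1[U2 + 1] * params$p_dropin) /
    denom
}

# enumerate the relative's genotype explicitly (at most one relative), then
# delegate the remaining unknowns to `inner`
with_relative <- function(relative, fixed, base_cond, n_unknown, locus_freqs,
                          params, inner) {
  if (n_unknown < 1)
    stop("a relative hypothesis consumes one unknown contributor")
  sg <- relative$suspect_g
  tot <- 0
  for (g in all_genotypes(names(locus_freqs))) {
    wg <- relative_genotype_prob(g, sg, relative$ibd, base_cond,
                                 params$theta, locus_freqs)
    if (wg == 0) next
    tot <- tot + wg * inner(add_counts(fixed, g), add_counts(base_cond, g),
                            n_unknown - 1L)
  }
  tot
}

#' Sum the evidence probability over unknown contributors
#'
#' Law-of-total-probability sum over all genotype assignments to the unknown
#' contributors, each weighted by its sequential theta-conditional sampling
#' probability and the drop-out/drop-in probability of the observed evidence.
#' Implemented as a dynamic program over allele-count vectors (see
#' [brute_force_sum()] for the reference enumeration it must agree with). A
#' relative of the suspected contributor, when hypothesized, is enumerated
#' explicitly over their possible genotypes via [relative_genotype_prob()].
#'
#' @param detected Character vector of detected evidence alleles (or a
#'   [locus_evidence()]).
#' @param fixed Allele counts of typed contributors subject to drop-out
#'   (i.e. the suspect when their side includes them); named numeric or
#'   character vector.
#' @param mask Assumed-contributor alleles detected in the evidence.
#' @param n_unknown Number of unknown contributors, 0 to 4.
#' @param relative Optional `list(ibd = ibd_triple(), suspect_g = genotype())`:
#'   one unknown is a relative of the suspect.
#' @param base_cond Conditioning counts for theta sampling (suspect plus
#'   assumed-contributor genotypes); unknown alleles drawn earlier in a term
#'   are added internally.
#' @param params [lr_params()].
#' @param locus_freqs Named numeric vector of floored frequencies; its names
#'   are the allele universe for the unknowns.
#' @return The summed evidence probability.
#' @export
sum_over_unknowns <- function(detected, fixed = NULL, mask = character(),
                              n_unknown, relative = NULL, base_cond = NULL,
                              params, locus_freqs) {
  if (inherits(detected, "locus_evidence")) detected <- detected$detected
  fixed <- as_counts(fixed)
  base_cond <- as_counts(base_cond)
  n_unknown <- as.integer(n_unknown)
  if (n_unknown < 0 || n_unknown > 4)
    stop("n_unknown must be between 0 and 4")
  if (length(locus_freqs) == 0) stop("empty allele universe at this locus")
  if (!is.null(relative)) {
    return(with_relative(relative, fixed, base_cond, n_unknown, locus_freqs,
                         params,
                         function(fx, bc, nu)
                           dp_unknowns(detected, fx, mask, nu, bc, params,
                                       locus_freqs)))
  }
  dp_unknowns(detected, fixed, mask, n_unknown, base_cond, params, locus_freqs)
}

#' Reference enumeration over unknown-contributor genotypes
#'
#' Naive nested sum over ordered tuples of unordered genotypes, one per
#' unknown contributor, with sequential theta-conditional genotype
#' probabilities ([genotype_prob()], each drawn genotype added to the
#' conditioning counts for the next). This is the definitional computation
#' that the dynamic program in [sum_over_unknowns()] must reproduce; it is
#' retained as an independent test oracle and guarded against combinatorial
#' blow-up.
#'
#' @inheritParams sum_over_unknowns
#' @return The summed evidence probability.
#' @export
brute_force_sum <- function(detected, fixed = NULL, mask = character(),
                            n_unknown, relative = NULL, base_cond = NULL,
                            params, locus_freqs) {
  if (inherits(detected, "locus_evidence")) detected <- detected$detected
  fixed <- as_counts(fixed)
  base_cond <- as_counts(base_cond)
  n_unknown <- as.integer(n_unknown)
  if (n_unknown < 0 || n_unknown > 4)
    stop("n_unknown must be between 0 and 4")
  n_g <- length(locus_freqs) * (length(locus_freqs) + 1) / 2
  n_free <- n_unknown - if (is.null(relative)) 0L else 1L
  if (n_g^max(n_free, 0) > 1e7)
    stop("genotype combinations exceed enumeration guard (1e7)")
  if (!is.null(relative)) {
    return(with_relative(relative, fixed, base_cond, n_unknown, locus_freqs,
                         params,
                         function(fx, bc, nu)
                           brute_force_sum(detected, fx, mask, nu, NULL, bc,
                                           params, locus_freqs)))
  }
  if (n_unknown == 0)
    return(locus_evidence_prob(detected, fixed, mask, params, locus_freqs))
  gts <- all_genotypes(names(locus_freqs))
  tot <- 0
  for (g in gts) {
    pg <- genotype_prob(g, base_cond, params$theta, locus_freqs)
    if (pg == 0) next
    tot <- tot + pg * brute_force_sum(detected, add_counts(fixed, g), mask,
                                      n_unknown - 1L, NULL,
                                      add_counts(base_cond, g), params,
                                      locus_freqs)
  }
  tot
}

#' Per-locus likelihood ratio
#'
#' Evaluates both sides of the hypothesis pair at one locus. The masking set
#' is the intersection of the assumed contributors' alleles with the detected
#' evidence alleles, applied identically on both sides. Theta conditioning
#' includes the suspect's genotype on *both* sides (population-level
#' relatedness between the suspect and the true contributor is exactly what
#' the correction models) plus all assumed genotypes.
#'
#' A zero denominator with a zero numerator reports LR = 1 with a warning; a
#' zero denominator with a positive numerator reports `Inf` with a warning.
#'
#' @param E [locus_evidence()] for the locus.
#' @param suspect_g The suspect's [genotype()] at this locus (`NULL` if no
#'   suspect is typed there; an error if a hypothesis side needs it).
#' @param assumed_gs List of assumed contributors' genotypes at this locus.
#' @param hyp [hypothesis_pair()].
#' @param params [lr_params()].
#' @param locus_freqs Named numeric vector of floored frequencies.
#' @return List with `numerator`, `denominator`, `lr`, and `warning`
#'   (`NA_character_` when clean).
#' @export
locus_lr <- function(E, suspect_g = NULL, assumed_gs = list(), hyp, params,
                     locus_freqs) {
  detected <- if (inherits(E, "locus_evidence")) E$detected else E
  assumed_alleles <- unlist(assumed_gs, use.names = FALSE)
  mask <- intersect(assumed_alleles, detected)
  base_cond <- as_counts(c(suspect_g, assumed_alleles))
  side <- function(h) {
    if (h$includes_suspect && is.null(suspect_g))
      stop("suspect genotype required at this locus but missing")
    fixed <- if (h$includes_suspect) as_counts(suspect_g) else NULL
    rel <- NULL
    if (!is.null(h$relative)) {
      if (is.null(suspect_g))
        stop("relative hypothesis requires the suspect's genotype for conditioning")
      rel <- list(ibd = h$relative, suspect_g = suspect_g)
    }
    sum_over_unknowns(detected, fixed, mask, h$n_unknowns, rel, base_cond,
                      params, locus_freqs)
  }
  num <- side(hyp$numerator)
  den <- side(hyp$denominator)
  if (den == 0) {
    if (num == 0)
      list(numerator = num, denominator = den, lr = 1,
           warning = "0/0 at this locus; LR reported as 1")
    else
      list(numerator = num, denominator = den, lr = Inf,
           warning = "zero denominator with positive numerator; LR is infinite")
  } else {
    list(numerator = num, denominator = den, lr = num / den,
         warning = NA_character_)
  }
}

#' Compute likelihood ratios for a full case
#'
#' For each population frequency table: flag the evidence and suspect alleles
#' at every analyzed marker, apply the 5/2n floor, compute the per-locus LR,
#' and multiply across loci. Only markers present in the evidence are
#' analyzed.
#'
#' @param evidence Named list (marker -> [locus_evidence()]).
#' @param suspect [reference_profile()] or `NULL`.
#' @param hyp [hypothesis_pair()] (assumed contributors ride along on it).
#' @param params [lr_params()].
#' @param tables A [frequency_table()] or list of them (one per population).
#' @return List of `lr_result` objects, one per population, each holding
#'   `population`, `per_locus` (named numeric), `per_locus_detail`,
#'   `overall`, `warnings`, `params`, and a text `hypothesis_desc`.
#' @export
compute_case <- function(evidence, suspect = NULL, hyp, params, tables) {
  if (inherits(tables, "frequency_table")) tables <- list(tables)
  markers <- names(evidence)
  flagged <- lapply(markers, function(m) {
    sg <- if (!is.null(suspect)) suspect$genotypes[[m]] else NULL
    unique(c(evidence[[m]]$detected, sg))
  })
  names(flagged) <- markers
  lapply(tables, function(tab) {
    fl <- apply_min_frequency(tab, flagged)
    per_locus <- stats::setNames(numeric(length(markers)), markers)
    detail <- vector("list", length(markers))
    names(detail) <- markers
    warns <- character()
    for (m in markers) {
      lf <- fl$freqs[[m]]
      if (is.null(lf))
        stop("marker ", m, " missing from frequency table '", tab$population,
             "'; run validate_case() first")
      sg <- if (!is.null(suspect)) suspect$genotypes[[m]] else NULL
      ags <- Filter(Negate(is.null),
                    lapply(hyp$assumed, function(p) p$genotypes[[m]]))
      r <- locus_lr(evidence[[m]], sg, ags, hyp, params, lf)
      per_locus[[m]] <- r$lr
      detail[[m]] <- r
      if (!is.na(r$warning)) warns <- c(warns, paste0(m, ": ", r$warning))
    }
    structure(list(population = tab$population,
                   per_locus = per_locus,
                   per_locus_detail = detail,
                   overall = prod(per_locus),
                   warnings = warns,
                   params = params,
                   hypothesis_desc = describe_hypothesis(hyp, suspect)),
              class = "lr_result")
  })
}

describe_hypothesis <- function(hyp, suspect = NULL) {
  one <- function(h) {
    parts <- character()
    if (h$includes_suspect)
      parts <- c(parts, paste0("suspect",
                               if (!is.null(suspect)) paste0(" (", suspect$sample_name, ")")))
    if (h$n_unknowns > 0) {
      if (!is.null(h$relative)) {
        parts <- c(parts, sprintf(
          "1 relative of suspect (k0=%g,k1=%g,k2=%g)",
          h$relative$k0, h$relative$k1, h$relative$k2))
        if (h$n_unknowns > 1)
          parts <- c(parts, sprintf("%d unknown(s)", h$n_unknowns - 1L))
      } else {
        parts <- c(parts, sprintf("%d unknown(s)", h$n_unknowns))
      }
    }
    if (length(parts) == 0) parts <- "no contributors"
    paste(parts, collapse = " + ")
  }
  assumed <- if (length(hyp$assumed))
    paste(vapply(hyp$assumed, function(p) p$sample_name, character(1)),
          collapse = ",")
  else "none"
  sprintf("H1: %s | H2: %s | assumed: %s",
          one(hyp$numerator), one(hyp$denominator), assumed)
}
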