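# Readers and writers for genetic-analyzer CSV exports (GeneMapper ID/ID-X,
# OSIRIS, GeneMarker dialects), long-format allele-frequency tables, and
# result files. Parsing is delegated to data.table::fread (which also
# tolerates a UTF-8 BOM); header matching is case-insensitive and tolerant
# of column-order permutations.

# exports in the wild are comma- or tab-delimited; decide from the header
# line (spreadsheet column names contain spaces, so fread's own sniffer is
# not restricted enough)
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an STR profile table
#'
#' Accepts CSV or tab-delimited exports with a header row containing
#' "Sample File" or "Sample Name", "Marker", and "Allele 1", "Allele 2", ...
#' columns; optional "Height 1", "Height 2", ... columns are captured and
#' must align with non-empty allele cells. Header matching is
#' case-insensitive and column order does not matter. Empty allele cells are
#' skipped; a marker row with no alleles at all is kept (complete locus
#' drop-out).
#'
#' @param path Path to the exported file.
#' @return Object of class `profile_table`: a list with `rows`, each row a
#'   list with `sample_name`, `marker`, `alleles` (ordered character vector)
#'   and `heights` (numeric, aligned with `alleles`, or `NULL`).
#' @export
read_profiles <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          sep = sniff_sep(path), fill = TRUE,
                          data.table = FALSE)
  hdr <- trimws(tolower(names(dt)))
  sample_col <- which(hdr %in% c("sample file", "sample name"))[1]
  marker_col <- which(hdr == "marker")[1]
  if (is.na(sample_col))
    stop("missing mandatory header: 'Sample File' or 'Sample Name'")
  if (is.na(marker_col)) stop("missing mandatory header: 'Marker'")
  am <- regmatches(hdr, regexec("^allele ?([0-9]+)$", hdr))
  hm <- regmatches(hdr, regexec("^height ?([0-9]+)$", hdr))
  allele_idx <- which(lengths(am) == 2)
  height_idx <- which(lengths(hm) == 2)
  if (length(allele_idx) == 0)
    stop("missing mandatory headers: 'Allele 1', 'Allele 2', ...")
  allele_k <- as.integer(vapply(am[allele_idx], `[`, character(1), 2))
  height_k <- as.integer(vapply(hm[height_idx], `[`, character(1), 2))
  allele_idx <- allele_idx[order(allele_k)]
  allele_k <- sort(allele_k)
  height_idx <- height_idx[order(height_k)]
  height_k <- sort(height_k)

  rows <- vector("list", nrow(dt))
  seen <- character()
  for (r in seq_len(nrow(dt))) {
    sample_name <- trimws(dt[r, sample_col])
    marker <- trimws(dt[r, marker_col])
    if (!nzchar(sample_name) && !nzchar(marker)) next
    key <- paste0(sample_name, "\r", marker)
    if (key %in% seen)
      stop("duplicate row for sample '", sample_name, "', marker '", marker, "'")
    seen <- c(seen, key)
    avals <- trimws(unlist(dt[r, allele_idx], use.names = FALSE))
    avals[is.na(avals)] <- ""
    hvals <- if (length(height_idx)) {
      h <- trimws(unlist(dt[r, height_idx], use.names = FALSE))
      h[is.na(h)] <- ""
      h
    } else character(0)
    keep <- nzchar(avals)
    heights <- NULL
    if (length(hvals) && any(nzchar(hvals))) {
      # heights must sit in column positions that carry an allele
      if (!all(height_k[nzchar(hvals)] %in% allele_k[keep]))
        stop("height without a matching allele for sample '", sample_name,
             "', marker '", marker, "'")
      pos <- match(allele_k[keep], height_k)  # height slot per kept allele
      hh <- rep(NA_real_, sum(keep))
      found <- !is.na(pos) & nzchar(hvals[ifelse(is.na(pos), 1L, pos)])
      hh[found] <- suppressWarnings(as.numeric(hvals[pos[found]]))
      heights <- hh
      if (all(is.na(heights))) heights <- NULL
    }
    rows[[r]] <- list(sample_name = sample_name, marker = marker,
                      alleles = avals[keep], heights = heights)
  }
  rows <- Filter(Negate(is.null), rows)
  structure(list(rows = rows), class = "profile_table")
}

#' Write a profile table in the exchange dialect
#'
#' Inverse of [read_profiles()] (lossless for alleles and heights); used by
#' the synthetic-data generator to produce on-disk fixtures.
#'
#' @param table A `profile_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(table, path) {
  n_allele <- max(c(1L, vapply(table$rows, function(r) length(r$alleles), integer(1))))
  has_heights <- any(vapply(table$rows, function(r) !is.null(r$heights), logical(1)))
  hdr <- c("Sample Name", "Marker", paste("Allele", seq_len(n_allele)),
           if (has_heights) paste("Height", seq_len(n_allele)))
  lines <- paste(hdr, collapse = ",")
  for (r in table$rows) {
    al <- c(r$alleles, rep("", n_allele - length(r$alleles)))
    ht <- if (has_heights) {
      h <- if (is.null(r$heights)) rep(NA_real_, length(r$alleles)) else r$heights
      h <- c(h, rep(NA_real_, n_allele - length(h)))
      ifelse(is.na(h), "", format_lr(h))
    }
    lines <- c(lines, paste(c(r$sample_name, r$marker, al, ht), collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract an evidence profile from a parsed table
#'
#' @param table A `profile_table` from [read_profiles()].
#' @param sample_name Which sample to extract.
#' @return Named list (marker -> [locus_evidence()]). Duplicate alleles
#'   within a row collapse to one detected allele (with a warning); rows with
#'   no alleles become empty detected sets (complete locus drop-out).
#' @export
to_evidence <- function(table, sample_name) {
  rows <- Filter(function(r) r$sample_name == sample_name, table$rows)
  if (length(rows) == 0) stop("sample '", sample_name, "' not found")
  out <- list()
  for (r in rows) {
    if (anyDuplicated(r$alleles))
      warning("duplicate allele(s) in sample '", sample_name, "' at ",
              r$marker, "; collapsed to a set")
    heights <- NULL
    if (!is.null(r$heights)) {
      keep <- !is.na(r$heights) & !duplicated(r$alleles)
      if (any(keep))
        heights <- stats::setNames(r$heights[keep], r$alleles[keep])
    }
    out[[r$marker]] <- locus_evidence(r$marker, r$alleles, heights)
  }
  out
}

#' Extract a reference profile from a parsed table
#'
#' @inheritParams to_evidence
#' @return A [reference_profile()]: one allele at a marker is read as a
#'   homozygote, two as a heterozygote; three or more is an error.
#' @export
to_reference <- function(table, sample_name) {
  rows <- Filter(function(r) r$sample_name == sample_name, table$rows)
  if (length(rows) == 0) stop("sample '", sample_name, "' not found")
  gts <- list()
  for (r in rows) {
    n <- length(r$alleles)
    if (n == 1) gts[[r$marker]] <- genotype(r$alleles[1])
    else if (n == 2) gts[[r$marker]] <- genotype(r$alleles[1], r$alleles[2])
    else stop("reference sample '", sample_name, "' has ", n, " alleles at ",
              r$marker, "; expected 1 or 2")
  }
  reference_profile(sample_name, gts)
}

#' Read a long-format allele-frequency table
#'
#' Expects a CSV with (case-insensitive) header `Marker,Allele,Frequency`,
#' one allele per row, frequencies as decimals in (0, 1].
#'
#' @param path Path to the CSV file.
#' @param population Population label to attach.
#' @param n_individuals Number of individuals behind the database (drives the
#'   5/2n floor).
#' @return A [frequency_table()].
#' @export
read_frequency_table <- function(path, population, n_individuals) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          sep = sniff_sep(path), data.table = FALSE)
  hdr <- trimws(tolower(names(dt)))
  mi <- match("marker", hdr); ai <- match("allele", hdr); fi <- match("frequency", hdr)
  if (any(is.na(c(mi, ai, fi))))
    stop("frequency file must have header 'Marker,Allele,Frequency'")
  marker <- trimws(dt[[mi]]); allele <- trimws(dt[[ai]])
  freq <- suppressWarnings(as.numeric(dt[[fi]]))
  if (any(is.na(freq))) stop("non-numeric frequency value")
  if (any(freq <= 0 | freq > 1))
    stop("frequencies must lie in (0, 1]")
  if (anyDuplicated(paste0(marker, "\r", allele)))
    stop("duplicate (marker, allele) row in frequency file")
  freqs <- lapply(split(stats::setNames(freq, allele), marker), identity)
  frequency_table(population, n_individuals, freqs)
}

#' Write likelihood-ratio results to CSV
#'
#' Emits a parameter-echo block (drop-out, drop-in, theta, alpha, hypothesis
#' description) followed by one row per marker with one LR column per
#' population and a final "Overall" row. Numbers are written at full
#' precision (round-trippable); infinite LRs serialize as `"inf"` with the
#' warnings column populated.
#'
#' @param results List of `lr_result` objects (one per population) from
#'   [compute_case()], or a list of such lists for sequential parameter
#'   sweeps (one block per element).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (length(results) && inherits(results[[1]], "lr_result"))
    results <- list(results)
  lines <- unlist(lapply(results, results_block_lines))
  writeLines(lines, path)
  invisible(path)
}

results_block_lines <- function(results) {
  p <- results[[1]]$params
  lines <- c("Parameter,Value",
             paste0("P(D_O),", format_lr(p$p_dropout)),
             paste0("P(D_I),", format_lr(p$p_dropin)),
             paste0("theta,", format_lr(p$theta)),
             paste0("alpha,", format_lr(p$alpha)),
             paste0("Hypotheses,\"", results[[1]]$hypothesis_desc, "\""),
             "")
  pops <- vapply(results, function(r) r$population, character(1))
  markers <- names(results[[1]]$per_locus)
  lines <- c(lines, paste(c("Marker", pops, "Warnings"), collapse = ","))
  for (m in markers) {
    vals <- vapply(results, function(r) format_lr(r$per_locus[[m]]), character(1))
    w <- unlist(lapply(results, function(r)
      grep(paste0("^", m, ": "), r$warnings, value = TRUE)))
    wtxt <- if (length(w)) paste0("\"", paste(unique(w), collapse = "; "), "\"") else ""
    lines <- c(lines, paste(c(m, vals, wtxt), collapse = ","))
  }
  overall <- vapply(results, function(r) format_lr(r$overall), character(1))
  c(lines, paste(c("Overall", overall, ""), collapse = ","), "")
}
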