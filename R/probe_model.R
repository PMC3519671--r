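#' Assemble a chip from a probe-level table
#'
#' A `chip_data` object holds all PM/MM probe pairs of a single array together
#' with a few layout summaries. Probes are organized in probe sets of typically
#' 11--20 pairs interrogating one transcript; within a set the probe index `k`
#' counts toward the 5'-end starting at 1 (i.e. `k = 1` is the probe nearest
#' the transcript 3'-end), and `L` is the distance in nucleotides between the
#' transcript 3'-end and the nearest base of the 25-mer probe.
#'
#' Probe sets with fewer than 3 valid pairs are excluded (subset statistics
#' over three consecutive probes are undefined for them). Probe pairs with a
#' missing PM or MM value are dropped; if MM is missing for the whole table the
#' chip is flagged PM-only and downstream hook fitting is disabled.
#'
#' @param probes data.frame with columns `probeset_id`, `k`, `pm` and
#'   optionally `L`, `mm`, `is_control`, `control_region`.
#' @param metadata free-form named list attached to the chip.
#' @param reverse_k set `TRUE` if the table uses vendor ordering (index counted
#'   from the 5'-end); indices are then reversed within each set so that
#'   `k = 1` is the most 3' probe.
#' @return object of class `chip_data` with elements `probes` (validated
#'   data.frame), `pm_only`, and `metadata`.
#' @export
chip_data <- function(probes, metadata = list(), reverse_k = FALSE) {
  stopifnot(is.data.frame(probes))
  required <- c("probeset_id", "k", "pm")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols))
    stop("probe table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  probes$probeset_id <- as.character(probes$probeset_id)
  probes$k <- as.integer(probes$k)
  if (is.null(probes$L)) probes$L <- NA_integer_
  if (is.null(probes$mm)) probes$mm <- NA_real_
  if (is.null(probes$is_control)) probes$is_control <- FALSE
  if (is.null(probes$control_region)) probes$control_region <- "none"
  probes$is_control <- as.logical(probes$is_control)
  probes$control_region <- as.character(probes$control_region)

  bad_region <- !probes$control_region %in% c("3prime", "middle", "5prime", "none")
  if (any(bad_region))
    stop("invalid control_region value(s): ",
         paste(unique(probes$control_region[bad_region]), collapse = ", "))

  pm_only <- all(is.na(probes$mm))

  # pairs with a missing intensity are dropped, not imputed
  keep <- !is.na(probes$pm) & (pm_only | !is.na(probes$mm))
  if (!all(keep)) {
    message(sum(!keep), " probe pair(s) with missing intensities dropped")
    probes <- probes[keep, , drop = FALSE]
  }
  if (!nrow(probes)) stop("no valid probe pairs")
  if (any(probes$pm <= 0))
    stop("non-positive PM intensity in probe set(s): ",
         paste(utils::head(unique(probes$probeset_id[probes$pm <= 0]), 5),
               collapse = ", "))
  if (!pm_only && any(probes$mm <= 0))
    stop("non-positive MM intensity in probe set(s): ",
         paste(utils::head(unique(probes$probeset_id[probes$mm <= 0]), 5),
               collapse = ", "))
  if (any(!is.na(probes$L) & probes$L < 0)) stop("negative probe position L")

  dup <- duplicated(probes[c("probeset_id", "k")])
  if (any(dup))
    stop("duplicate (probeset_id, k): ",
         paste(utils::head(paste(probes$probeset_id[dup], probes$k[dup], sep = "/"), 5),
               collapse = ", "))

  if (reverse_k) {
    probes$k <- stats::ave(probes$k, probes$probeset_id,
                           FUN = function(x) max(x) + 1L - x)
  }

  sizes <- table(probes$probeset_id)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    message(length(small), " probe set(s) with fewer than 3 pairs excluded")
    probes <- probes[!probes$probeset_id %in% small, , drop = FALSE]
  }
  if (!nrow(probes)) stop("no probe set with >= 3 probe pairs")

  probes <- probes[order(probes$probeset_id, probes$k), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(probes = probes, pm_only = pm_only, metadata = metadata),
            class = "chip_data")
}

#' @export
print.chip_data <- function(x, ...) {
  cat("chip_data:", length(unique(x$probes$probeset_id)), "probe sets,",
      nrow(x$probes), "probe pairs",
      if (x$pm_only) "(PM-only)" else "(PM/MM)", "\n")
  if (any(x$probes$is_control))
    cat("  control sets:",
        length(unique(x$probes$probeset_id[x$probes$is_control])), "\n")
  invisible(x)
}

#' Number of probe sets on a chip
#' @param chip a `chip_data` object.
#' @return integer count of probe sets.
#' @export
n_psets <- function(chip) length(unique(chip$probes$probeset_id))

#' Typical probe-set size
#' @param chip a `chip_data` object.
#' @return the modal number of probe pairs per set.
#' @export
pset_size <- function(chip) {
  sizes <- table(table(chip$probes$probeset_id))
  as.integer(names(sizes)[which.max(sizes)])
}

.check_seq <- function(s, what) {
  s <- toupper(s)
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s))
    stop(what, " contains characters outside {A,C,G,T,U}")
  s
}

#' Probe distance to the transcript 3'-end
#'
#' Locates a 25-mer probe in its target sequence (given 5' to 3') by exact
#' matching and returns `L`, the number of nucleotides between the transcript
#' 3'-end and the nearest (most 3') matched base. A probe abutting the 3'
#' terminus has `L = 0`. If the probe matches at several positions the most 3'
#' match (smallest `L`) is used and a warning is issued.
#'
#' @param probe_seq character, the 25-mer probe sequence.
#' @param target_seq character, the target transcript sequence (5' to 3').
#' @return integer distance `L >= 0`.
#' @export
compute_probe_position <- function(probe_seq, target_seq) {
  probe_seq <- .check_seq(probe_seq, "probe sequence")
  target_seq <- .check_seq(target_seq, "target sequence")
  if (nchar(probe_seq) != 25) stop("probe sequence must be a 25-mer")
  hits <- gregexpr(probe_seq, target_seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) stop("probe not found in target sequence")
  if (length(hits) > 1)
    warning("probe matches target at ", length(hits),
            " positions; using the most 3' match")
  start <- max(hits)
  as.integer(nchar(target_seq) - (start + 24L))
}

#' Probe positions for a chip from FASTA sequences
#'
#' Convenience wrapper mapping every probe of a chip onto its target using
#' [compute_probe_position()]. Sequence names in the target FASTA must equal
#' the `probeset_id`s; the probe FASTA must be named `<probeset_id>.<k>`.
#'
#' @param probe_fasta,target_fasta paths to FASTA files.
#' @return data.frame with columns `probeset_id`, `k`, `L`.
#' @export
probe_positions_from_fasta <- function(probe_fasta, target_fasta) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA input")
  probes <- Biostrings::readDNAStringSet(probe_fasta)
  targets <- Biostrings::readDNAStringSet(target_fasta)
  ids <- sub("\\.[0-9]+$", "", names(probes))
  ks <- as.integer(sub("^.*\\.", "", names(probes)))
  if (anyNA(ks)) stop("probe FASTA names must follow <probeset_id>.<k>")
  missing_t <- setdiff(unique(ids), names(targets))
  if (length(missing_t))
    stop("no target sequence for probe set(s): ",
         paste(utils::head(missing_t, 5), collapse = ", "))
  L <- mapply(function(p, id)
    compute_probe_position(as.character(p), as.character(targets[[id]])),
    as.list(as.character(probes)), ids)
  data.frame(probeset_id = ids, k = ks, L = as.integer(L))
}

#' Mean probe spacing per index increment
#'
#' The probe layout of 3'-expression arrays places consecutive probe indices at
#' roughly constant nucleotide distance from each other; the spacing (in
#' nucleotides per index increment) converts index-scale decay constants into
#' nucleotide-scale ones. Three estimators are returned: the least-squares
#' slope of the median `L` per index versus `k` (primary), the
#' vanishing-intercept ratio `<L>/<k>` over all probes, and the two-point
#' estimator `(<L_last> - <L_1>)/(N_pset - 1)`.
#'
#' @param chip a `chip_data` object with `L` present for all probes.
#' @return list with elements `slope`, `ratio`, `two_point`, and the per-index
#'   medians in `median_L`.
#' @export
mean_probe_spacing <- function(chip) {
  p <- chip$probes[!chip$probes$is_control, , drop = FALSE]
  if (anyNA(p$L)) stop("probe positions L missing; cannot estimate spacing")
  ks <- sort(unique(p$k))
  if (length(ks) < 2) stop("need at least 2 distinct probe indices")
  med <- tapply(p$L, p$k, stats::median)
  fit <- stats::lm(med ~ ks)
  slope <- unname(stats::coef(fit)[2])
  ratio <- mean(p$L) / mean(p$k)
  kmax <- max(ks)
  two_point <- (mean(p$L[p$k == kmax]) - mean(p$L[p$k == min(ks)])) /
    (kmax - min(ks))
  if (isTRUE(all.equal(stats::var(p$L), 0)))
    warning("degenerate layout: all probe positions identical")
  list(slope = slope, ratio = ratio, two_point = two_point,
       median_L = med)
}

#' Classify a probe set by its positional span
#'
#' Probe sets are grouped by whether their first (most 3') and last probes lie
#' close to the transcript 3'-end. Sets covering only the region near the
#' 3'-end (low `L_first`, low `L_last`) are empirically more prone to
#' non-specific hybridization.
#'
#' @param L_first,L_last positions of the first and last probe of the set.
#' @param low_first,low_last cutoffs below which the respective position counts
#'   as "low" (defaults 100 and 500 nt).
#' @return one of `"LL"`, `"LH"`, `"HH"`, `"HL"`.
#' @export
classify_probeset_span <- function(L_first, L_last,
                                   low_first = 100, low_last = 500) {
  if (any(c(L_first, L_last) < 0)) stop("positions must be non-negative")
  if (L_first > L_last) stop("L_first must not exceed L_last")
  first_low <- L_first < low_first
  last_low <- L_last < low_last
  if (first_low && last_low) "LL"
  else if (first_low) "LH"
  else if (!last_low) "HH"
  else "HL"
}
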