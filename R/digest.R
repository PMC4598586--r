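#' Restriction enzymes
#'
#' A restriction enzyme is described by its recognition sequence and the
#' top-strand cut offset within the site. The two built-ins are the pair used
#' for the double digest: SacI (GAGCT^C, offset 5) and MseI (T^TAA,
#' offset 1); both sites are palindromic. Overhangs are ignored for length
#' accounting since fragments are sized on a gel.
#'
#' @param name Enzyme name.
#' @param site Recognition sequence over A/C/G/T.
#' @param cut_offset Top-strand cut position in bases from the site start
#'   (0 to nchar(site)).
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  stopifnot(grepl("^[ACGT]+$", site),
            cut_offset >= 0, cut_offset <= nchar(site))
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
re_saci <- function() restriction_enzyme("SacI", "GAGCTC", 5L)

#' @rdname restriction_enzyme
#' @export
re_msei <- function() restriction_enzyme("MseI", "TTAA", 1L)

#' Size-selection parameters for the reduced representation
#'
#' @param min_length,max_length Inclusive fragment length bounds in bp
#'   (defaults 250-500, the gel cut used by the protocol).
#' @param require_mixed_ends Keep only fragments with one SacI and one MseI
#'   boundary; mirrors the dual-adaptor design in which only mixed-end
#'   fragments amplify. Chromosome-end fragments are never retained under
#'   this rule.
#' @return An object of class `digest_params`.
#' @export
digest_params <- function(min_length = 250L, max_length = 500L,
                          require_mixed_ends = TRUE) {
  stopifnot(min_length > 0, min_length <= max_length)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 require_mixed_ends = isTRUE(require_mixed_ends)),
            class = "digest_params")
}

#' Find restriction cut positions in a sequence
#'
#' Returns the sorted 0-based top-strand cut coordinates (site start + cut
#' offset) of every occurrence of the recognition sequence, including
#' overlapping occurrences. Sites containing N never match.
#'
#' @param sequence A single DNA string.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of 0-based cut positions.
#' @export
find_sites <- function(sequence, enzyme) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  m <- gregexpr(paste0("(?=", enzyme$site, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  sort(as.integer(m) - 1L + enzyme$cut_offset)
}

#' Double restriction digest of a genome
#'
#' Cuts every chromosome at all sites of two enzymes and returns the
#' fragments between consecutive cuts (plus chromosome ends). Fragments tile
#' each chromosome exactly, and each boundary is labelled with the enzyme
#' that produced it (`chrom_end` for chromosome ends).
#'
#' @param ref Named character vector of chromosome sequences.
#' @param enz_a,enz_b Two distinct [restriction_enzyme()] objects.
#' @return Tibble with columns chrom, start, end (0-based half-open),
#'   left_enzyme, right_enzyme, length.
#' @export
double_digest <- function(ref, enz_a = re_saci(), enz_b = re_msei()) {
  stop_if_not_ref(ref)
  stopifnot(enz_a$name != enz_b$name)
  out <- lapply(names(ref), function(chrom) {
    s <- ref[[chrom]]
    L <- nchar(s)
    ca <- find_sites(s, enz_a)
    cb <- find_sites(s, enz_b)
    cuts <- c(ca, cb)
    labs <- c(rep(enz_a$name, length(ca)), rep(enz_b$name, length(cb)))
    ord <- order(cuts)
    cuts <- cuts[ord]; labs <- labs[ord]
    # drop duplicate cut coordinates (overlapping sites of both enzymes)
    keep <- !duplicated(cuts)
    cuts <- cuts[keep]; labs <- labs[keep]
    # cuts at 0 or L coincide with chromosome ends
    inner <- cuts > 0 & cuts < L
    cuts <- cuts[inner]; labs <- labs[inner]
    bounds <- c(0L, cuts, L)
    blabs <- c("chrom_end", labs, "chrom_end")
    n <- length(bounds) - 1L
    tibble::tibble(chrom = chrom,
                   start = bounds[seq_len(n)],
                   end = bounds[seq_len(n) + 1L],
                   left_enzyme = blabs[seq_len(n)],
                   right_enzyme = blabs[seq_len(n) + 1L],
                   length = bounds[seq_len(n) + 1L] - bounds[seq_len(n)])
  })
  dplyr::bind_rows(out)
}

#' Size-select the reduced representation
#'
#' Retains fragments whose length lies within the inclusive
#' `[min_length, max_length]` window and, when `require_mixed_ends` is set,
#' whose two boundaries come from the two different enzymes (either order).
#'
#' @param fragments Fragment tibble from [double_digest()].
#' @param params A [digest_params()].
#' @return The retained subset of `fragments`.
#' @export
select_representation <- function(fragments, params = digest_params()) {
  keep <- fragments$length >= params$min_length &
    fragments$length <= params$max_length
  if (params$require_mixed_ends) {
    keep <- keep & fragments$left_enzyme != fragments$right_enzyme &
      fragments$left_enzyme != "chrom_end" &
      fragments$right_enzyme != "chrom_end"
  }
  fragments[keep, , drop = FALSE]
}

# Captured windows: first read_len bases inward from each fragment end,
# clipped at the fragment middle (short fragments are covered whole, once).
capture_windows <- function(fragments, read_len) {
  short <- fragments$length <= 2L * read_len
  left <- tibble::tibble(chrom = fragments$chrom, start = fragments$start,
                         end = pmin(fragments$start + read_len, fragments$end))
  right <- tibble::tibble(chrom = fragments$chrom,
                          start = pmax(fragments$end - read_len,
                                       fragments$start),
                          end = fragments$end)
  win <- dplyr::bind_rows(left[!short, ], right[!short, ],
                          tibble::tibble(chrom = fragments$chrom[short],
                                         start = fragments$start[short],
                                         end = fragments$end[short]))
  if (nrow(win) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(win$start + 1L, win$end)))
}

#' Capture statistics of the reduced representation
#'
#' Reports, for each cytosine context, how many genomic sites fall within the
#' captured windows (the first `read_len` bases inward from each selected
#' fragment end, clipped at the fragment middle) and how the captured sites
#' distribute over genic, TE and other regions — the in-silico digestion
#' analysis used to check that a reduced representation samples contexts
#' proportionally.
#'
#' @param fragments Selected fragment tibble.
#' @param ref Named character vector of chromosome sequences.
#' @param ann Annotation tibble (gene and te rows are used).
#' @param read_len Post-trim read span in bp (default 75).
#' @return List of class `capture_report` with `summary` (per-context totals,
#'   captured counts and fractions), `regions` (per-context breakdown of
#'   captured sites over genic/te/other) and `windows` (GRanges).
#' @export
capture_stats <- function(fragments, ref, ann, read_len = 75L) {
  stopifnot(read_len > 0)
  catalog <- classify_cytosines(ref)
  win <- capture_windows(fragments, read_len)
  gr <- GenomicRanges::GRanges(catalog$chrom,
                               IRanges::IRanges(catalog$pos + 1L, width = 1L))
  captured <- IRanges::overlapsAny(gr, win)
  summary <- catalog |>
    dplyr::mutate(captured = captured) |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(total_sites = dplyr::n(),
                     captured_sites = sum(.data$captured),
                     captured_fraction = mean(.data$captured),
                     .groups = "drop")
  region_of <- function(sub) {
    region <- rep("other", nrow(sub))
    for (ty in c("te", "gene")) {
      feats <- dplyr::filter(ann, .data$type == ty)
      if (nrow(feats) == 0) next
      fgr <- GenomicRanges::GRanges(feats$chrom,
                                    IRanges::IRanges(feats$start + 1L,
                                                     feats$end))
      hit <- IRanges::overlapsAny(
        GenomicRanges::GRanges(sub$chrom,
                               IRanges::IRanges(sub$pos + 1L, width = 1L)),
        fgr)
      region[hit & region == "other"] <- if (ty == "gene") "genic" else "te"
    }
    region
  }
  cap <- catalog[captured, , drop = FALSE]
  regions <- if (nrow(cap) > 0) {
    cap$region <- region_of(cap)
    cap |>
      dplyr::count(.data$context, .data$region, name = "sites") |>
      dplyr::group_by(.data$context) |>
      dplyr::mutate(fraction = .data$sites / sum(.data$sites)) |>
      dplyr::ungroup()
  } else {
    tibble::tibble(context = character(), region = character(),
                   sites = integer(), fraction = numeric())
  }
  structure(list(summary = summary, regions = regions, windows = win),
            class = "capture_report")
}

#' @export
print.capture_report <- function(x, ...) {
  cat("<capture_report>\n")
  print(x$summary)
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}
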