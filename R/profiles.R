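#' Sliding-window methylation profile
#'
#' Chromosome-scale profile over sliding windows (default 200 kb advancing by
#' 100 kb, i.e. 100 kb overlap): per window and context the unweighted mean
#' of called site levels and the site count, plus the total repeat bases
#' (tandem/inverted repeat annotation clipped to the window). The last
#' partial window is included.
#'
#' @param calls Site calls from [call_levels()] (or masked calls).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param ann Optional annotation tibble; rows of type tandem_repeat /
#'   inverted_repeat contribute to `repeat_bases`.
#' @param win,step Window and step size in bp (`win >= step`).
#' @return Tibble of class `meth_windows`: chrom, start, end, context,
#'   mean_level, n_sites, repeat_bases.
#' @export
window_profile <- function(calls, chrom_lengths, ann = NULL,
                           win = 200000L, step = 100000L) {
  stopifnot(win >= step, step > 0)
  wins <- dplyr::bind_rows(lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    starts <- seq(0L, max(L - 1L, 0L), by = step)
    tibble::tibble(chrom = chrom, start = as.integer(starts),
                   end = as.integer(pmin(starts + win, L)))
  }))
  wins$window_id <- seq_len(nrow(wins))
  gr_w <- GenomicRanges::GRanges(wins$chrom,
                                 IRanges::IRanges(wins$start + 1L, wins$end))
  stats_tbl <- NULL
  if (nrow(calls) > 0) {
    gr_s <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$pos + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(gr_s, gr_w)
    stats_tbl <- tibble::tibble(
      window_id = wins$window_id[S4Vectors::subjectHits(ov)],
      context = calls$context[S4Vectors::queryHits(ov)],
      level = calls$level[S4Vectors::queryHits(ov)]) |>
      dplyr::group_by(.data$window_id, .data$context) |>
      dplyr::summarise(mean_level = mean(.data$level),
                       n_sites = dplyr::n(), .groups = "drop")
  }
  grid <- tidyr::expand_grid(window_id = wins$window_id,
                             context = c("CG", "CHG", "CHH"))
  out <- dplyr::left_join(grid, stats_tbl %||%
                            tibble::tibble(window_id = integer(),
                                           context = character(),
                                           mean_level = numeric(),
                                           n_sites = integer()),
                          by = c("window_id", "context")) |>
    dplyr::mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L)) |>
    dplyr::left_join(wins, by = "window_id")
  rep_bases <- rep(0L, nrow(wins))
  if (!is.null(ann)) {
    reps <- dplyr::filter(ann, .data$type %in% c("tandem_repeat",
                                                 "inverted_repeat"))
    if (nrow(reps) > 0) {
      gr_r <- GenomicRanges::GRanges(reps$chrom,
                                     IRanges::IRanges(reps$start + 1L,
                                                      reps$end))
      ov <- GenomicRanges::findOverlaps(gr_r, gr_w)
      if (length(ov) > 0) {
        inter_w <- IRanges::width(IRanges::pintersect(
          GenomicRanges::ranges(gr_r)[S4Vectors::queryHits(ov)],
          GenomicRanges::ranges(gr_w)[S4Vectors::subjectHits(ov)]))
        agg <- tapply(inter_w, S4Vectors::subjectHits(ov), sum)
        rep_bases[as.integer(names(agg))] <- as.integer(agg)
      }
    }
  }
  out$repeat_bases <- rep_bases[out$window_id]
  out <- dplyr::select(out, "chrom", "start", "end", "context",
                       "mean_level", "n_sites", "repeat_bases")
  class(out) <- c("meth_windows", class(out))
  out
}

#' Mean methylation per genomic component
#'
#' Pooled methylation per gene-anatomy component and context over the six
#' components: 1 kb upstream, 200 bp promoter (immediately upstream of the
#' TSS), exon, intron, 1 kb downstream, and TE body. Components are
#' strand-aware (a minus-strand gene's promoter lies above its highest
#' coordinate). A site overlapped by the same component type of several genes
#' is counted once for that component; a site can contribute to several
#' different component types.
#'
#' @param calls Site calls from [call_levels()].
#' @param ann Annotation tibble.
#' @param chrom_lengths Named integer vector of chromosome lengths (for
#'   clipping flanks).
#' @param promoter,flank Component geometry in bp.
#' @return Tibble of class `component_means`: component, context, n_sites,
#'   mean_level (unweighted site mean), meth, unmeth, pooled_level
#'   (read-count pooled).
#' @export
component_means <- function(calls, ann, chrom_lengths,
                            promoter = 200L, flank = 1000L) {
  comps <- component_granges(ann, chrom_lengths, promoter, flank,
                             split_flanks = TRUE)
  gr_s <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1L, width = 1L))
  rows <- lapply(names(comps), function(nm) {
    if (length(comps[[nm]]) == 0) return(NULL)
    hit <- IRanges::overlapsAny(gr_s, GenomicRanges::reduce(comps[[nm]]))
    sub <- calls[hit, ]
    if (nrow(sub) == 0) return(NULL)
    sub |>
      dplyr::group_by(.data$context) |>
      dplyr::summarise(n_sites = dplyr::n(),
                       mean_level = mean(.data$level),
                       meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                       .groups = "drop") |>
      dplyr::mutate(component = nm, .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(pooled_level = .data$meth / (.data$meth + .data$unmeth))
  class(out) <- c("component_means", class(out))
  out
}

#' Metagene / meta-TE methylation profile
#'
#' Length-normalised profile over feature bodies plus fixed flanks: each
#' feature body is split into `body_bins` equal bins (10% of feature length
#' each by default; remainder bases go to the last bin) and each 1 kb flank
#' into fixed `flank_bin`-bp bins. Minus-strand features are mirrored so bin
#' 1 is always the 5' end. Features shorter than `body_bins` bases are
#' excluded (count recorded in `attr(, "excluded_short")`).
#'
#' @param calls Site calls from [call_levels()].
#' @param features Feature tibble (rows with chrom/start/end/strand), e.g.
#'   gene or te rows of the annotation.
#' @param flank Flank span in bp (default 1000).
#' @param body_bins Number of body bins (default 10).
#' @param flank_bin Flank bin width in bp (default 100).
#' @return Tibble of class `meth_metagene`: region (upstream/body/
#'   downstream), bin (1-based within region, 5' to 3'), context, mean_level,
#'   n_sites.
#' @export
metagene_profile <- function(calls, features, flank = 1000L, body_bins = 10L,
                             flank_bin = 100L) {
  too_short <- (features$end - features$start) < body_bins
  n_excluded <- sum(too_short)
  feats <- features[!too_short, , drop = FALSE]
  n_flank_bins <- as.integer(ceiling(flank / flank_bin))
  empty <- tibble::tibble(region = character(), bin = integer(),
                          context = character(), mean_level = numeric(),
                          n_sites = integer())
  if (nrow(feats) == 0 || nrow(calls) == 0) {
    attr(empty, "excluded_short") <- n_excluded
    class(empty) <- c("meth_metagene", class(empty))
    return(empty)
  }
  gr_s <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1L, width = 1L))
  span <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(pmax(feats$start - flank, 0L) + 1L,
                                  feats$end + flank))
  ov <- GenomicRanges::findOverlaps(gr_s, span)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  pos <- calls$pos[qi]
  fs <- feats$start[si]; fe <- feats$end[si]
  flen <- fe - fs
  minus <- feats$strand[si] == "-"
  # signed distance from the 5' end of the feature (negative = upstream)
  d5 <- ifelse(minus, fe - 1L - pos, pos - fs)
  region <- dplyr::case_when(d5 < 0 ~ "upstream",
                             d5 >= flen ~ "downstream",
                             TRUE ~ "body")
  binw <- pmax(flen %/% body_bins, 1L)
  bin <- dplyr::case_when(
    region == "upstream" ~ pmin((-d5 - 1L) %/% flank_bin + 1L, n_flank_bins),
    region == "downstream" ~ pmin((d5 - flen) %/% flank_bin + 1L,
                                  n_flank_bins),
    TRUE ~ pmin(d5 %/% binw + 1L, body_bins))
  # upstream bins are numbered 5'->3' (bin 1 farthest from the feature)
  bin[region == "upstream"] <- n_flank_bins + 1L -
    bin[region == "upstream"]
  prof <- tibble::tibble(region = region, bin = as.integer(bin),
                         context = calls$context[qi],
                         level = calls$level[qi]) |>
    dplyr::filter(!(region == "upstream" & -d5 > flank),
                  !(region == "downstream" & d5 - flen >= flank)) |>
    dplyr::group_by(.data$region, .data$bin, .data$context) |>
    dplyr::summarise(mean_level = mean(.data$level), n_sites = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(region = factor(.data$region,
                                  levels = c("upstream", "body",
                                             "downstream"))) |>
    dplyr::arrange(.data$region, .data$bin, .data$context)
  attr(prof, "excluded_short") <- n_excluded
  class(prof) <- c("meth_metagene", class(prof))
  prof
}

#' Per-context methylation level histogram
#'
#' Counts called sites into an exact-zero class plus ten 10-percent bins
#' `(0,10], ..., (90,100]`, per context; fractions sum to one. This is the
#' single-base-resolution view in which plant CG methylation is bimodal
#' (mass at 0 and in the (90,100] class).
#'
#' @param calls Site calls from [call_levels()].
#' @return Tibble of class `meth_histogram`: context, bin (ordered factor),
#'   n_sites, fraction.
#' @export
level_histogram <- function(calls) {
  bins <- c("0", paste0("(", seq(0, 90, 10), ",", seq(10, 100, 10), "]"))
  lab <- ifelse(calls$level == 0, "0",
                as.character(cut(calls$level * 100,
                                 breaks = seq(0, 100, 10),
                                 labels = bins[-1], include.lowest = FALSE)))
  out <- tibble::tibble(context = calls$context,
                        bin = factor(lab, levels = bins)) |>
    dplyr::count(.data$context, .data$bin, name = "n_sites",
                 .drop = FALSE) |>
    dplyr::group_by(.data$context) |>
    dplyr::mutate(fraction = .data$n_sites / sum(.data$n_sites)) |>
    dplyr::ungroup()
  class(out) <- c("meth_histogram", class(out))
  out
}
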