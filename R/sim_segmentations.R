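# Chromatin-state segmentations for nine cell lines and mappability
# tracks (uniqueness / alignability) for the fixture genome.

CELL_LINES <- c("GM12878", "H1hESC", "K562", "HepG2", "HUVEC",
                "HMEC", "HSMM", "NHEK", "NHLF")
ECTO_LINES <- c("NHEK", "HMEC")

#' Simulate chromatin-state segmentations for nine cell lines
#'
#' One BED-style state table per cell line with `Strong_Enhancer`,
#' `Active_Promoter` and filler (`Heterochrom`) elements. Element counts
#' differ across cell lines. The two ectodermally derived lines (NHEK,
#' HMEC) additionally receive an enhancer planted near the start of every
#' planted novel transcript, so novel lncRNAs are genuinely closer to
#' ectodermal enhancers.
#'
#' @param config a [fixture_config()].
#' @return a `segmentation_bundle`: list with `tracks` (named list of
#'   data.frames `chrom`, `start`, `end`, `state`), `cell_lines`,
#'   `ecto_lines`, and `sidecar` (planted element counts per line/state).
#' @export
simulate_segmentations <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  layout <- fixture_layout(config)
  glen <- config$chrom_length_bp
  chroms <- layout$chrom_names

  # novel transcript start positions (leftmost exon start)
  nov <- layout$planted[startsWith(layout$planted$label, "novel_"), ,
                        drop = FALSE]
  nov_starts <- do.call(rbind, lapply(nov$planted_id, function(id) {
    e <- layout$planted_exons[layout$planted_exons$planted_id == id, ,
                              drop = FALSE]
    data.frame(chrom = e$chrom[1L], pos = min(e$start),
               stringsAsFactors = FALSE)
  }))

  with_seed(sub_seed(config$seed, 61L), {
    tracks <- list()
    sidecar <- list()
    for (i in seq_along(CELL_LINES)) {
      cl <- CELL_LINES[i]
      # counts deliberately differ by line
      n_enh <- 80L + 15L * i
      n_prom <- 60L + 10L * i
      n_fill <- 40L
      mk <- function(n, width_range, state) {
        chrom <- sample(chroms, n, replace = TRUE)
        w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
        s <- vapply(seq_len(n), function(k)
          sample.int(glen - w[k] - 2000L, 1L) + 1000L, 1L)
        data.frame(chrom = chrom, start = s, end = s + w - 1L,
                   state = state, stringsAsFactors = FALSE)
      }
      df <- rbind(mk(n_enh, c(200L, 1200L), "Strong_Enhancer"),
                  mk(n_prom, c(200L, 800L), "Active_Promoter"),
                  mk(n_fill, c(1000L, 5000L), "Heterochrom"))
      if (cl %in% ECTO_LINES && nrow(nov_starts)) {
        off <- sample(200:800, nrow(nov_starts), replace = TRUE)
        df <- rbind(df, data.frame(
          chrom = nov_starts$chrom,
          start = pmax(1L, nov_starts$pos - off - 400L),
          end = pmax(1L, nov_starts$pos - off),
          state = "Strong_Enhancer", stringsAsFactors = FALSE))
      }
      df <- df[order(df$chrom, df$start), , drop = FALSE]
      rownames(df) <- NULL
      tracks[[cl]] <- df
      sidecar[[cl]] <- data.frame(
        cell_line = cl,
        n_enhancer = sum(df$state == "Strong_Enhancer"),
        n_promoter = sum(df$state == "Active_Promoter"),
        stringsAsFactors = FALSE)
    }
    structure(list(tracks = tracks, cell_lines = CELL_LINES,
                   ecto_lines = ECTO_LINES,
                   sidecar = do.call(rbind, sidecar)),
              class = "segmentation_bundle")
  })
}

#' Write segmentations as one BED file per cell line
#'
#' BED uses 0-based half-open coordinates; conversion happens here at the
#' I/O boundary.
#'
#' @param seg a `segmentation_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_segmentations <- function(seg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(seg$tracks)) {
    df <- seg$tracks[[cl]]
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start - 1L, df$end,
                       df$state),
               file.path(dir, paste0(cl, ".bed")))
  }
  write_tsv(seg$sidecar, file.path(dir, "element_counts.tsv"))
  invisible(dir)
}

#' Read a chromatin-state BED file
#'
#' Uses [rtracklayer::import()] and returns 1-based inclusive intervals
#' with the state label from the name column.
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `state`.
#' @export
read_segmentation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             state = gr$name, stringsAsFactors = FALSE)
}

#' Simulate mappability tracks
#'
#' Uniqueness (35-mer) and alignability (75-mer) stand-in tracks: score 1
#' genome-wide except over planted low-mappability regions, which score
#' 0.5 in both tracks.
#'
#' @param config a [fixture_config()].
#' @return list with `uniqueness` and `alignability`, each a data.frame
#'   `chrom`, `start`, `end`, `score` (1-based inclusive intervals).
#' @export
simulate_mappability <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  layout <- fixture_layout(config)
  glen <- config$chrom_length_bp
  one_track <- function() {
    out <- list()
    for (ch in layout$chrom_names) {
      low <- layout$lowmap_regions[layout$lowmap_regions$chrom == ch, ,
                                   drop = FALSE]
      low <- low[order(low$start), , drop = FALSE]
      pos <- 1L
      rows <- list()
      if (nrow(low)) {
        for (r in seq_len(nrow(low))) {
          if (low$start[r] > pos)
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = ch, start = pos, end = low$start[r] - 1L, score = 1,
              stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, start = low$start[r], end = low$end[r], score = 0.5,
            stringsAsFactors = FALSE)
          pos <- low$end[r] + 1L
        }
      }
      if (pos <= glen)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = glen, score = 1,
          stringsAsFactors = FALSE)
      out[[ch]] <- do.call(rbind, rows)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  }
  list(uniqueness = one_track(), alignability = one_track())
}

#' Write a mappability track as bedGraph
#' @param track data.frame `chrom`, `start`, `end`, `score` (1-based).
#' @param path output path (bedGraph, 0-based half-open).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start - 1L,
                     track$end, track$score), path)
  invisible(path)
}

#' Read a mappability track (bedGraph or wiggle)
#'
#' Accepts bedGraph and fixed-step wiggle via [rtracklayer::import()];
#' the format is inferred from the file extension (`.bedgraph`/`.bg` vs
#' `.wig`).
#'
#' @param path track file path.
#' @return data.frame `chrom`, `start`, `end`, `score` (1-based inclusive).
#' @export
read_track <- function(path) {
  fmt <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) "wig"
         else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             score = gr$score, stringsAsFactors = FALSE)
}
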