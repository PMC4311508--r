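# Per-sample assembled transcript models (ab initio assembler-style GTF
# stand-ins) plus the ground-truth sidecar used as the test oracle.

#' Generate per-sample transcript assemblies
#'
#' Emits one exon table per sample. Annotated reference transcripts are
#' assembled in every sample; each planted novel transcript and artifact
#' appears in a controlled fraction of samples
#' (`config$novel_presence_fraction`), exercising the recurrence filter.
#' Assembled novel transcripts carry unknown strand (`"."`): their true
#' strand is only recoverable from splice-site motifs in the genome.
#' Ground-truth labels, presence counts and planted distances are recorded
#' in the `truth` sidecar; every transcript carries exactly one label.
#'
#' @param config a [fixture_config()].
#' @param reference the `annotation` element of [generate_reference()]
#'   (used for the annotated transcripts; must come from the same config).
#' @param genome the genome from [generate_reference()] (unused here, kept
#'   for interface symmetry and validated for chromosome coverage).
#' @return an `assembly_bundle`: list with `per_sample` (named list of exon
#'   tables), `samples`, `groups`, `truth`, `truth_exons`.
#' @export
generate_sample_assemblies <- function(config, reference, genome = NULL) {
  stopifnot(inherits(config, "fixture_config"),
            inherits(reference, "reference_annotation"))
  layout <- fixture_layout(config)
  if (!is.null(genome) &&
      !all(layout$chrom_names %in% names(genome)))
    stopf("generate_sample_assemblies: genome does not cover fixture chromosomes")
  n <- config$n_samples
  samples <- c(sprintf("NN%03d", seq_len(config$n_samples_NN)),
               sprintf("PN%03d", seq_len(config$n_samples_PN)),
               sprintf("PP%03d", seq_len(config$n_samples_PP)))
  groups <- stats::setNames(
    c(rep("NN", config$n_samples_NN), rep("PN", config$n_samples_PN),
      rep("PP", config$n_samples_PP)), samples)

  k_present <- max(1L, as.integer(round(config$novel_presence_fraction * n)))
  if (config$novel_presence_fraction * n < 1)
    stopf("generate_sample_assemblies: presence fraction %.3f of %d samples is below 1 sample",
          config$novel_presence_fraction, n)

  planted <- layout$planted
  with_seed(sub_seed(config$seed, 31L), {
    presence_sets <- lapply(seq_len(nrow(planted)), function(i)
      sort(sample(samples, k_present)))
    names(presence_sets) <- planted$planted_id

    # annotated transcripts: present in every sample, true strand reported
    ann_ex <- reference$exons
    ann_tab <- data.frame(chrom = ann_ex$chrom, start = ann_ex$start,
                          end = ann_ex$end, strand = ann_ex$strand,
                          transcript_id = ann_ex$transcript_id,
                          stringsAsFactors = FALSE)

    # planted transcripts: strand hidden ("."), recovered via splice sites
    pl_ex <- layout$planted_exons
    pl_tab <- data.frame(chrom = pl_ex$chrom, start = pl_ex$start,
                         end = pl_ex$end, strand = ".",
                         transcript_id = pl_ex$planted_id,
                         stringsAsFactors = FALSE)

    per_sample <- lapply(samples, function(s) {
      keep <- vapply(presence_sets, function(set) s %in% set, TRUE)
      ids <- names(presence_sets)[keep]
      rbind(ann_tab, pl_tab[pl_tab$transcript_id %in% ids, , drop = FALSE])
    })
    names(per_sample) <- samples

    truth_ann <- data.frame(
      planted_id = unique(ann_ex$transcript_id),
      label = biotype_category(
        reference$genes$biotype[match(
          ann_ex$gene_id[match(unique(ann_ex$transcript_id),
                               ann_ex$transcript_id)],
          reference$genes$gene_id)]),
      chrom = ann_ex$chrom[match(unique(ann_ex$transcript_id),
                                 ann_ex$transcript_id)],
      strand = ann_ex$strand[match(unique(ann_ex$transcript_id),
                                   ann_ex$transcript_id)],
      detail = NA_real_,
      presence_n = n,
      stringsAsFactors = FALSE)
    truth_pl <- planted
    truth_pl$presence_n <- k_present
    truth <- rbind(truth_ann,
                   truth_pl[, c("planted_id", "label", "chrom", "strand",
                                "detail", "presence_n")])
    rownames(truth) <- NULL

    ann_truth_exons <- data.frame(planted_id = ann_ex$transcript_id,
                                  chrom = ann_ex$chrom,
                                  strand = ann_ex$strand,
                                  start = ann_ex$start, end = ann_ex$end,
                                  stringsAsFactors = FALSE)
    truth_exons <- rbind(ann_truth_exons, layout$planted_exons)
    rownames(truth_exons) <- NULL

    structure(list(per_sample = per_sample, samples = samples,
                   groups = groups, truth = truth,
                   truth_exons = truth_exons,
                   presence = presence_sets),
              class = "assembly_bundle")
  })
}

#' @export
print.assembly_bundle <- function(x, ...) {
  cat("assembly_bundle: ", length(x$per_sample), " samples, ",
      nrow(x$truth), " distinct transcripts\n", sep = "")
  invisible(x)
}

#' Write an assembly bundle to disk
#'
#' One GTF per sample plus the ground-truth sidecar TSV
#' (`truth.tsv`: `planted_id`, `label`, `chrom`, `strand`, `detail`,
#' `presence_n`).
#'
#' @param bundle an `assembly_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_assembly_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(bundle$per_sample)) {
    df <- bundle$per_sample[[s]]
    df <- df[order(df$chrom, df$start, df$transcript_id), , drop = FALSE]
    lines <- sprintf(
      '%s\tlncskin\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      df$chrom, df$start, df$end, df$strand, df$transcript_id,
      df$transcript_id)
    writeLines(lines, file.path(dir, paste0(s, ".gtf")))
  }
  write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  write_tsv(data.frame(sample_id = bundle$samples,
                       group = unname(bundle$groups[bundle$samples])),
            file.path(dir, "groups.tsv"))
  invisible(dir)
}

#' Map consensus catalog transcripts to planted ground-truth transcripts
#'
#' Matches each consensus model to the planted transcript whose exon
#' footprint it covers (same chromosome, overlapping span). Planted
#' transcripts are disjoint by construction, so the mapping is 1:1 for
#' every recovered transcript.
#'
#' @param catalog an `lnc_catalog`.
#' @param bundle the `assembly_bundle` the catalog was built from.
#' @return data.frame with `transcript_id`, `planted_id`, `label`.
#' @export
map_to_truth <- function(catalog, bundle) {
  tx <- catalog$transcripts
  truth_spans <- do.call(rbind, lapply(
    split(bundle$truth_exons, bundle$truth_exons$planted_id),
    function(e) data.frame(planted_id = e$planted_id[1L],
                           chrom = e$chrom[1L],
                           start = min(e$start), end = max(e$end),
                           stringsAsFactors = FALSE)))
  # exact span match first (consensus exons are unions of identical
  # planted copies, so spans agree exactly); fall back to largest overlap
  tx_key <- paste(tx$chrom, tx$start, tx$end)
  tr_key <- paste(truth_spans$chrom, truth_spans$start, truth_spans$end)
  m <- match(tx_key, tr_key)
  out <- data.frame(transcript_id = tx$transcript_id[!is.na(m)],
                    planted_id = truth_spans$planted_id[m[!is.na(m)]],
                    stringsAsFactors = FALSE)
  left <- which(is.na(m))
  if (length(left)) {
    tx_gr <- GenomicRanges::GRanges(tx$chrom[left],
                                    IRanges::IRanges(tx$start[left],
                                                     tx$end[left]))
    tr_gr <- GenomicRanges::GRanges(truth_spans$chrom,
                                    IRanges::IRanges(truth_spans$start,
                                                     truth_spans$end))
    hits <- GenomicRanges::findOverlaps(tx_gr, tr_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(tx_gr[qh],
                                                           tr_gr[sh]))
      best <- tapply(seq_along(qh), qh, function(ii) ii[which.max(ov[ii])])
      qh_b <- qh[unlist(best)]; sh_b <- sh[unlist(best)]
      out <- rbind(out, data.frame(
        transcript_id = tx$transcript_id[left][qh_b],
        planted_id = truth_spans$planted_id[sh_b],
        stringsAsFactors = FALSE))
    }
  }
  out$label <- bundle$truth$label[match(out$planted_id,
                                        bundle$truth$planted_id)]
  out
}
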