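# Synthetic reference annotation + genome.
#
# All placements (reference genes, planted novel transcripts, planted
# artifacts, low-mappability regions) are computed by one deterministic
# layout function so that generate_reference() and
# generate_sample_assemblies() agree on coordinates without sharing
# hidden state: both derive the layout from the config alone.

GENE_GAP <- 30000L       # bp between adjacent placed features
CHROM_MARGIN <- 50000L   # bp kept free at each chromosome end

# Deterministic genome layout for a fixture config.
# Returns reference gene models, planted novel/artifact transcript models
# with ground-truth labels, low-mappability regions, and the full intron
# list (used to write canonical splice-site motifs into the genome).
fixture_layout <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(sub_seed(config$seed, 11L), {
    k_nov <- config$n_novel_per_subtype
    need_coding <- 2L * k_nov + config$n_antisense + config$n_artifacts_premature
    if (config$n_coding_genes < need_coding)
      stopf("fixture layout: need >= %d coding genes to host %d intronic + %d interleaving novels, %d antisense partners and %d premature artifacts (got %d)",
            need_coding, k_nov, k_nov, config$n_antisense,
            config$n_artifacts_premature, config$n_coding_genes)
    if (config$n_annotated_lncRNAs < k_nov)
      stopf("fixture layout: need >= %d annotated lncRNAs to host encompassing novels (got %d)",
            k_nov, config$n_annotated_lncRNAs)

    genes <- list(); ref_exons <- list()
    planted <- list(); planted_exons <- list()
    lowmap <- list()

    # --- build slot plan -------------------------------------------------
    # every independently placed feature is a "slot"; hosted features
    # (intronic/interleaving novels, antisense partners, premature
    # artifacts) ride inside/next to their host coding gene's slot.
    slot_types <- c(
      rep("coding", config$n_coding_genes),
      rep("lncRNA", config$n_annotated_lncRNAs),
      rep("pseudogene", config$n_pseudogenes),
      rep("novel_intergenic", k_nov),
      rep("artifact_lowmap", config$n_artifacts_lowmap),
      rep("artifact_short", config$n_artifacts_short)
    )
    slot_types <- sample(slot_types)   # interleave feature types

    # host assignment: coding genes in placement order take hosted roles
    coding_roles <- c(rep("host_intronic", k_nov),
                      rep("host_interleaving", k_nov),
                      rep("host_antisense", config$n_antisense),
                      rep("host_premature", config$n_artifacts_premature),
                      rep("plain",
                          config$n_coding_genes - need_coding))
    coding_roles <- sample(coding_roles)
    # first k_nov lncRNAs in placement order are single-exon hosts that
    # planted encompassing novels engulf
    lnc_roles <- sample(c(rep("host_encompassing", k_nov),
                          rep("plain", config$n_annotated_lncRNAs - k_nov)))

    chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
    cursor <- CHROM_MARGIN
    chrom_i <- 1L
    i_coding <- 0L; i_lnc <- 0L; i_pseudo <- 0L; i_anti <- 0L
    i_novi <- 0L; i_novg <- 0L; i_novl <- 0L; i_nove <- 0L
    i_prem <- 0L; i_lowm <- 0L; i_short <- 0L

    add_exons <- function(gene_id, tx_id, chrom, strand, starts, ends) {
      data.frame(gene_id = gene_id, transcript_id = tx_id, chrom = chrom,
                 strand = strand, start = starts, end = ends,
                 stringsAsFactors = FALSE)
    }

    for (st in slot_types) {
      strand <- sample(c("+", "-"), 1L)
      if (st == "coding") {
        i_coding <- i_coding + 1L
        role <- coding_roles[i_coding]
        gid <- sprintf("PCG%04d", i_coding)
        exon_lens <- sample(300:1200, 3L, replace = TRUE)
        intron_lens <- sample(8000:12000, 2L, replace = TRUE)
        width <- sum(exon_lens) + sum(intron_lens)
      } else if (st == "lncRNA") {
        i_lnc <- i_lnc + 1L
        role <- lnc_roles[i_lnc]
        gid <- sprintf("LNC%04d", i_lnc)
        if (role == "host_encompassing") {
          exon_lens <- sample(400:800, 1L)
          intron_lens <- integer(0)
        } else {
          exon_lens <- sample(300:800, 2L, replace = TRUE)
          intron_lens <- sample(3000:6000, 1L)
        }
        width <- sum(exon_lens) + sum(intron_lens)
      } else if (st == "pseudogene") {
        i_pseudo <- i_pseudo + 1L
        role <- "plain"
        gid <- sprintf("PSG%04d", i_pseudo)
        exon_lens <- sample(600:2000, 1L)
        intron_lens <- integer(0)
        width <- exon_lens
      } else if (st == "novel_intergenic") {
        exon_lens <- sample(300:800, 2L, replace = TRUE)
        intron_lens <- sample(1000:2500, 1L)
        width <- sum(exon_lens) + sum(intron_lens)
      } else if (st == "artifact_lowmap") {
        exon_lens <- sample(300:800, 2L, replace = TRUE)
        intron_lens <- sample(1000:2500, 1L)
        width <- sum(exon_lens) + sum(intron_lens)
      } else { # artifact_short
        exon_lens <- 150L
        intron_lens <- integer(0)
        width <- exon_lens
      }
      # extra room for hosted features hanging off the 3' genomic end
      extra <- if (st == "coding") 6000L else 0L

      if (cursor + width + extra + GENE_GAP >
          config$chrom_length_bp - CHROM_MARGIN) {
        chrom_i <- chrom_i + 1L
        cursor <- CHROM_MARGIN
        if (chrom_i > config$n_chromosomes)
          stopf("fixture layout: chromosomes too short (%d x %d bp) to place the requested features; increase chrom_length_bp or n_chromosomes",
                config$n_chromosomes, config$chrom_length_bp)
      }
      chrom <- chrom_names[chrom_i]
      start <- as.integer(cursor)

      # exon coordinates for this slot's own transcript
      starts <- integer(length(exon_lens)); ends <- integer(length(exon_lens))
      pos <- start
      for (e in seq_along(exon_lens)) {
        starts[e] <- pos
        ends[e] <- pos + exon_lens[e] - 1L
        pos <- ends[e] + 1L + if (e <= length(intron_lens)) intron_lens[e] else 0L
      }
      span_end <- ends[length(ends)]

      if (st %in% c("coding", "lncRNA", "pseudogene")) {
        biotype <- switch(st, coding = "protein_coding", lncRNA = "lincRNA",
                          pseudogene = "pseudogene")
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, biotype = biotype, chrom = chrom, strand = strand,
          start = start, end = span_end, stringsAsFactors = FALSE)
        ref_exons[[length(ref_exons) + 1L]] <-
          add_exons(gid, paste0(gid, ".t1"), chrom, strand, starts, ends)
      }

      if (st == "coding" && role == "host_antisense") {
        # single-exon gene on the opposite strand overlapping exon 2
        i_anti <- i_anti + 1L
        agid <- sprintf("ASG%04d", i_anti)
        astrand <- if (strand == "+") "-" else "+"
        alen <- sample(300:600, 1L)
        astart <- starts[2L] + 50L
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = agid, biotype = "antisense", chrom = chrom,
          strand = astrand, start = astart, end = astart + alen - 1L,
          stringsAsFactors = FALSE)
        ref_exons[[length(ref_exons) + 1L]] <-
          add_exons(agid, paste0(agid, ".t1"), chrom, astrand,
                    astart, astart + alen - 1L)
      }

      if (st == "coding" && role == "host_intronic") {
        # two-exon novel centered in intron 1, >= 2 kb from flanking exons
        i_novi <- i_novi + 1L
        nid <- sprintf("NOVI%02d", i_novi)
        nstrand <- sample(c("+", "-"), 1L)
        ilen <- intron_lens[1L]
        inner <- 400L + 1200L + 400L
        off <- (ilen - inner) %/% 2L
        e1s <- ends[1L] + 1L + off
        ne_starts <- c(e1s, e1s + 400L + 1200L)
        ne_ends <- ne_starts + 400L - 1L
        planted[[length(planted) + 1L]] <- data.frame(
          planted_id = nid, label = "novel_intronic", chrom = chrom,
          strand = nstrand, detail = NA_real_, stringsAsFactors = FALSE)
        planted_exons[[length(planted_exons) + 1L]] <- data.frame(
          planted_id = nid, chrom = chrom, strand = nstrand,
          start = ne_starts, end = ne_ends, stringsAsFactors = FALSE)
      }

      if (st == "coding" && role == "host_interleaving") {
        # exon 1 centered in the last intron, exon 2 beyond the gene end
        i_novl <- i_novl + 1L
        nid <- sprintf("NOVL%02d", i_novl)
        nstrand <- sample(c("+", "-"), 1L)
        ilen <- intron_lens[2L]
        off <- (ilen - 400L) %/% 2L
        e1s <- ends[2L] + 1L + off
        e2s <- span_end + sample(2500:4000, 1L)
        planted[[length(planted) + 1L]] <- data.frame(
          planted_id = nid, label = "novel_interleaving", chrom = chrom,
          strand = nstrand, detail = NA_real_, stringsAsFactors = FALSE)
        planted_exons[[length(planted_exons) + 1L]] <- data.frame(
          planted_id = nid, chrom = chrom, strand = nstrand,
          start = c(e1s, e2s), end = c(e1s + 400L - 1L, e2s + 400L - 1L),
          stringsAsFactors = FALSE)
      }

      if (st == "coding" && role == "host_premature") {
        # mono-exon fragment < 2 kb downstream of the terminal exon
        i_prem <- i_prem + 1L
        nid <- sprintf("ARTP%02d", i_prem)
        d <- sample(200:1500, 1L)
        fs <- span_end + d + 1L
        planted[[length(planted) + 1L]] <- data.frame(
          planted_id = nid, label = "artifact_premature", chrom = chrom,
          strand = strand, detail = as.numeric(d), stringsAsFactors = FALSE)
        planted_exons[[length(planted_exons) + 1L]] <- data.frame(
          planted_id = nid, chrom = chrom, strand = strand,
          start = fs, end = fs + 300L - 1L, stringsAsFactors = FALSE)
      }

      if (st == "lncRNA" && role == "host_encompassing") {
        # novel transcript whose two exons flank the whole single-exon gene
        i_nove <- i_nove + 1L
        nid <- sprintf("NOVE%02d", i_nove)
        nstrand <- sample(c("+", "-"), 1L)
        e1e <- start - 3000L
        e2s <- span_end + 3000L
        planted[[length(planted) + 1L]] <- data.frame(
          planted_id = nid, label = "novel_encompassing", chrom = chrom,
          strand = nstrand, detail = NA_real_, stringsAsFactors = FALSE)
        planted_exons[[length(planted_exons) + 1L]] <- data.frame(
          planted_id = nid, chrom = chrom, strand = nstrand,
          start = c(e1e - 400L + 1L, e2s), end = c(e1e, e2s + 400L - 1L),
          stringsAsFactors = FALSE)
      }

      if (st == "novel_intergenic") {
        i_novg <- i_novg + 1L
        nid <- sprintf("NOVG%02d", i_novg)
        planted[[length(planted) + 1L]] <- data.frame(
          planted_id = nid, label = "novel_intergenic", chrom = chrom,
          strand = strand, detail = NA_real_, stringsAsFactors = FALSE)
        planted_exons[[length(planted_exons) + 1L]] <- data.frame(
          planted_id = nid, chrom = chrom, strand = strand,
          start = starts, end = ends, stringsAsFactors = FALSE)
      }

      if (st == "artifact_lowmap") {
        i_lowm <- i_lowm + 1L
        nid <- sprintf("ARTM%02d", i_lowm)
        planted[[length(planted) + 1L]] <- data.frame(
          planted_id = nid, label = "artifact_lowmap", chrom = chrom,
          strand = strand, detail = NA_real_, stringsAsFactors = FALSE)
        planted_exons[[length(planted_exons) + 1L]] <- data.frame(
          planted_id = nid, chrom = chrom, strand = strand,
          start = starts, end = ends, stringsAsFactors = FALSE)
        lowmap[[length(lowmap) + 1L]] <- data.frame(
          chrom = chrom, start = start - 500L, end = span_end + 500L,
          stringsAsFactors = FALSE)
      }

      if (st == "artifact_short") {
        i_short <- i_short + 1L
        nid <- sprintf("ARTS%02d", i_short)
        planted[[length(planted) + 1L]] <- data.frame(
          planted_id = nid, label = "artifact_short", chrom = chrom,
          strand = strand, detail = NA_real_, stringsAsFactors = FALSE)
        planted_exons[[length(planted_exons) + 1L]] <- data.frame(
          planted_id = nid, chrom = chrom, strand = strand,
          start = starts, end = ends, stringsAsFactors = FALSE)
      }

      cursor <- span_end + extra + GENE_GAP
    }

    genes <- do.call(rbind, genes)
    ref_exons <- do.call(rbind, ref_exons)
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(planted_id = character(), label = character(),
                 chrom = character(), strand = character(),
                 detail = numeric(), stringsAsFactors = FALSE)
    planted_exons <- if (length(planted_exons)) do.call(rbind, planted_exons) else
      data.frame(planted_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    lowmap <- if (length(lowmap)) do.call(rbind, lowmap) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    rownames(genes) <- rownames(ref_exons) <- NULL
    rownames(planted) <- rownames(planted_exons) <- NULL

    # intron list (reference + planted) for splice-motif writing
    intron_of <- function(ex) {
      key <- if ("transcript_id" %in% names(ex)) ex$transcript_id else ex$planted_id
      out <- list()
      for (tid in unique(key)) {
        e <- ex[key == tid, , drop = FALSE]
        e <- e[order(e$start), , drop = FALSE]
        if (nrow(e) < 2L) next
        out[[tid]] <- data.frame(
          chrom = e$chrom[-nrow(e)], strand = e$strand[-nrow(e)],
          start = e$end[-nrow(e)] + 1L, end = e$start[-1L] - 1L,
          stringsAsFactors = FALSE)
      }
      if (length(out)) do.call(rbind, out) else
        data.frame(chrom = character(), strand = character(),
                   start = integer(), end = integer(), stringsAsFactors = FALSE)
    }
    introns <- rbind(intron_of(ref_exons), intron_of(planted_exons))
    rownames(introns) <- NULL

    list(chrom_names = chrom_names, genes = genes, ref_exons = ref_exons,
         planted = planted, planted_exons = planted_exons,
         lowmap_regions = lowmap, introns = introns)
  })
}

#' Generate the synthetic reference annotation and genome
#'
#' Builds a small reference annotation (protein-coding, lincRNA, pseudogene
#' and antisense biotypes; genes non-overlapping except planted antisense
#' pairs) and a matching genome sequence in which every planted intron
#' carries the canonical GT..AG splice motif on its transcript's strand,
#' so splice-site strand inference can be exercised.
#'
#' @param config a [fixture_config()].
#' @return list with `annotation` (a `reference_annotation`, see
#'   [reference_annotation()]) and `genome` (a named
#'   [Biostrings::DNAStringSet]).
#' @export
generate_reference <- function(config) {
  layout <- fixture_layout(config)
  genome <- with_seed(sub_seed(config$seed, 23L), {
    seqs <- lapply(layout$chrom_names, function(ch) {
      paste0(sample(c("A", "C", "G", "T"), config$chrom_length_bp,
                    replace = TRUE), collapse = "")
    })
    names(seqs) <- layout$chrom_names
    Biostrings::DNAStringSet(unlist(seqs))
  })
  # write canonical splice motifs at every planted intron
  intr <- layout$introns
  if (nrow(intr)) {
    for (ch in unique(intr$chrom)) {
      s <- genome[[ch]]
      ii <- intr[intr$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(ii))) {
        if (ii$strand[r] == "+") {
          # forward read of the intron is GT....AG
          s <- Biostrings::replaceLetterAt(
            s, c(ii$start[r], ii$start[r] + 1L, ii$end[r] - 1L, ii$end[r]),
            c("G", "T", "A", "G"))
        } else {
          # reverse-complement read is GT....AG  =>  forward CT....AC
          s <- Biostrings::replaceLetterAt(
            s, c(ii$start[r], ii$start[r] + 1L, ii$end[r] - 1L, ii$end[r]),
            c("C", "T", "A", "C"))
        }
      }
      genome[[ch]] <- s
    }
  }
  annotation <- reference_annotation(layout$genes, layout$ref_exons)
  list(annotation = annotation, genome = genome)
}

#' Write a reference annotation to a GTF file
#'
#' Serializes gene/transcript/exon records with `gene_id`, `transcript_id`
#' and `gene_biotype` attributes (1-based inclusive coordinates). The
#' writer is deterministic: identical annotations give identical bytes.
#'
#' @param ref a `reference_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_gtf <- function(ref, path) {
  ex <- ref$exons
  ex <- ex[order(ex$chrom, ex$start, ex$transcript_id), , drop = FALSE]
  bt <- stats::setNames(ref$genes$biotype, ref$genes$gene_id)
  lines <- sprintf(
    '%s\tlncskin\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$chrom, ex$start, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    bt[ex$gene_id])
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome to a FASTA file
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
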