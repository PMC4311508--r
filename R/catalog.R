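# Transcript catalog: merge per-sample assemblies, infer strand from
# splice-site motifs, classify against the reference annotation.

#' Build an indexed reference annotation
#'
#' Validates the gene/exon tables and precomputes the interval indices the
#' classifier and filters query: exon ranges, gene spans, and the derived
#' intronic space (union of gene spans minus union of exons).
#'
#' @param genes data.frame with columns `gene_id`, `biotype`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive).
#' @param exons data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`.
#' @return an object of class `reference_annotation`.
#' @export
reference_annotation <- function(genes, exons) {
  stopifnot(all(c("gene_id", "biotype", "chrom", "strand", "start", "end")
                %in% names(genes)),
            all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(exons)))
  if (any(exons$end < exons$start))
    stopf("reference_annotation: exon with end < start")
  if (!all(exons$gene_id %in% genes$gene_id))
    stopf("reference_annotation: exon references unknown gene_id")
  exon_gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand, gene_id = exons$gene_id)
  span_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id,
    biotype = genes$biotype)
  spans_red <- GenomicRanges::reduce(span_gr, ignore.strand = TRUE)
  exons_red <- GenomicRanges::reduce(exon_gr, ignore.strand = TRUE)
  intronic <- GenomicRanges::setdiff(spans_red, exons_red,
                                     ignore.strand = TRUE)
  structure(list(genes = genes, exons = exons, exon_gr = exon_gr,
                 span_gr = span_gr, intronic_space = intronic,
                 gene_space = spans_red),
            class = "reference_annotation")
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat("reference_annotation: ", nrow(x$genes), " genes (",
      paste(sprintf("%s=%d", names(table(x$genes$biotype)),
                    as.integer(table(x$genes$biotype))), collapse = ", "),
      "), ", nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

# map a reference biotype to a catalog category label
biotype_category <- function(biotype) {
  ifelse(biotype == "protein_coding", "protein_coding",
  ifelse(biotype == "pseudogene", "pseudogene",
  ifelse(biotype == "antisense", "antisense", "annotated_ncRNA")))
}

CATEGORY_LEVELS <- c("protein_coding", "antisense", "pseudogene",
                     "annotated_ncRNA", "novel_intronic", "novel_intergenic",
                     "novel_interleaving", "novel_encompassing")

#' Merge per-sample assemblies into consensus transcript models
#'
#' Transcripts assembled in different samples are merged into one consensus
#' model when they lie on the same chromosome and strand and either share
#' an identical intron chain (multi-exon) or overlap by at least 1 bp
#' (mono-exon; overlap is chained transitively). Consensus exons are the
#' union of the merged exon footprints; sample presence is the union of
#' contributing samples. The result is ordered by genomic position, so the
#' consensus set is invariant to sample input order.
#'
#' @param bundle an assembly bundle as returned by
#'   [generate_sample_assemblies()], or any list with `$per_sample`, a named
#'   list of per-sample exon tables (`chrom`, `start`, `end`, `strand`,
#'   `transcript_id`; strand `"."` or `"*"` for unknown).
#' @return a `transcript_models` object: list with `transcripts` (one row
#'   per consensus model), `exons`, and `presence` (named list of sample id
#'   vectors).
#' @export
merge_assemblies <- function(bundle) {
  per_sample <- bundle$per_sample
  stopifnot(is.list(per_sample), length(names(per_sample)) == length(per_sample))
  rows <- lapply(names(per_sample), function(s) {
    df <- per_sample[[s]]
    if (any(df$end < df$start)) {
      bad <- which(df$end < df$start)[1L]
      stopf("merge_assemblies: sample '%s' record %d has end < start", s, bad)
    }
    df$sample_id <- s
    df
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    return(structure(list(
      transcripts = data.frame(transcript_id = character(),
                               chrom = character(), strand = character(),
                               start = integer(), end = integer(),
                               n_exons = integer(), mature_length = integer(),
                               n_samples = integer(), stringsAsFactors = FALSE),
      exons = data.frame(transcript_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE),
      presence = list()), class = "transcript_models"))
  }
  rows$strand[!(rows$strand %in% c("+", "-"))] <- "*"
  rows$tx_key <- paste(rows$sample_id, rows$transcript_id, sep = "\r")

  # per input transcript: ordered exons -> intron-chain signature
  ord <- order(rows$tx_key, rows$start)
  rows <- rows[ord, , drop = FALSE]
  split_idx <- split(seq_len(nrow(rows)), rows$tx_key)
  sig <- character(length(split_idx))
  mono_first <- integer(0)
  for (i in seq_along(split_idx)) {
    idx <- split_idx[[i]]
    e <- rows[idx, , drop = FALSE]
    if (nrow(e) == 1L) {
      sig[i] <- NA_character_   # mono-exon: merged by overlap below
    } else {
      sig[i] <- paste0(e$chrom[1L], "|", e$strand[1L], "|",
                       paste(e$end[-nrow(e)] + 1L, e$start[-1L] - 1L,
                             sep = "-", collapse = ","))
    }
  }
  tx_keys <- names(split_idx)

  group <- character(length(split_idx))
  multi <- !is.na(sig)
  group[multi] <- sig[multi]

  # mono-exon clustering: transitive >= 1 bp overlap on same chrom+strand
  if (any(!multi)) {
    mono_i <- which(!multi)
    mono_ex <- do.call(rbind, lapply(mono_i, function(i) {
      rows[split_idx[[i]][1L], c("chrom", "start", "end", "strand")]
    }))
    gr <- GenomicRanges::GRanges(
      paste(mono_ex$chrom, mono_ex$strand, sep = "|"),
      IRanges::IRanges(mono_ex$start, mono_ex$end))
    # min.gapwidth = 0: merge on >= 1 shared base, never on adjacency
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, red)
    cl <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    group[mono_i] <- paste0("mono:", as.character(GenomicRanges::seqnames(red))[cl],
                            ":", GenomicRanges::start(red)[cl])
  }

  # consensus per group: union exon footprint, union of samples
  groups <- split(seq_along(tx_keys), group)
  cons <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    member_rows <- unlist(split_idx[groups[[g]]], use.names = FALSE)
    e <- rows[member_rows, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      e$chrom[1L], IRanges::IRanges(e$start, e$end)))
    cons[[g]] <- list(
      chrom = e$chrom[1L], strand = e$strand[1L],
      starts = GenomicRanges::start(gr), ends = GenomicRanges::end(gr),
      samples = sort(unique(e$sample_id)))
  }
  o <- order(vapply(cons, `[[`, "", "chrom"),
             vapply(cons, function(x) x$starts[1L], 1L),
             vapply(cons, function(x) x$ends[length(x$ends)], 1L),
             vapply(cons, `[[`, "", "strand"))
  cons <- cons[o]
  ids <- sprintf("TCONS%05d", seq_along(cons))

  transcripts <- data.frame(
    transcript_id = ids,
    chrom = vapply(cons, `[[`, "", "chrom"),
    strand = vapply(cons, `[[`, "", "strand"),
    start = vapply(cons, function(x) x$starts[1L], 1L),
    end = vapply(cons, function(x) x$ends[length(x$ends)], 1L),
    n_exons = vapply(cons, function(x) length(x$starts), 1L),
    mature_length = vapply(cons, function(x)
      sum(x$ends - x$starts + 1L), 1L),
    n_samples = vapply(cons, function(x) length(x$samples), 1L),
    stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_along(cons), function(i) {
    data.frame(transcript_id = ids[i], chrom = cons[[i]]$chrom,
               strand = cons[[i]]$strand, start = cons[[i]]$starts,
               end = cons[[i]]$ends, stringsAsFactors = FALSE)
  }))
  presence <- stats::setNames(lapply(cons, `[[`, "samples"), ids)
  structure(list(transcripts = transcripts, exons = exons,
                 presence = presence),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models: ", nrow(x$transcripts), " consensus transcripts\n",
      sep = "")
  invisible(x)
}

#' Infer transcript strand from splice-site motifs
#'
#' For a multi-exon transcript, returns `"+"` if every intron reads
#' `GT..AG` on the forward genomic strand, `"-"` if every intron's
#' reverse complement reads `GT..AG` (forward `CT..AC`), and `"unknown"`
#' otherwise. Mono-exon transcripts are always `"unknown"`: splice sites
#' are the only strand evidence used.
#'
#' @param exons data.frame of the transcript's exons (`chrom`, `start`,
#'   `end`), one chromosome.
#' @param genome named [Biostrings::DNAStringSet] covering the transcript.
#' @return `"+"`, `"-"`, or `"unknown"`.
#' @export
infer_strand <- function(exons, genome) {
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) < 2L) return("unknown")
  chrom <- exons$chrom[1L]
  if (!chrom %in% names(genome))
    stopf("infer_strand: chromosome '%s' absent from genome", chrom)
  seq <- genome[[chrom]]
  if (max(exons$end) > length(seq))
    stopf("infer_strand: exon end %d beyond chromosome '%s' end (%d)",
          max(exons$end), chrom, length(seq))
  istart <- exons$end[-nrow(exons)] + 1L
  iend <- exons$start[-1L] - 1L
  if (any(iend < istart + 3L)) return("unknown")
  donor <- as.character(Biostrings::extractAt(
    seq, IRanges::IRanges(istart, istart + 1L)))
  accept <- as.character(Biostrings::extractAt(
    seq, IRanges::IRanges(iend - 1L, iend)))
  if (all(donor == "GT") && all(accept == "AG")) return("+")
  if (all(donor == "CT") && all(accept == "AC")) return("-")
  "unknown"
}

# Vectorized classifier over a transcript_models object.
# Returns data.frame(transcript_id, category, flagged).
classify_models <- function(models, ref) {
  tx <- models$transcripts
  ex <- models$exons
  n <- nrow(tx)
  if (n == 0L)
    return(data.frame(transcript_id = character(), category = character(),
                      flagged = logical(), stringsAsFactors = FALSE))
  ex_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  tx_index <- match(ex$transcript_id, tx$transcript_id)

  # --- annotated / antisense: exonic overlap with reference exons -------
  hits <- GenomicRanges::findOverlaps(ex_gr, ref$exon_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ref_strand <- as.character(GenomicRanges::strand(ref$exon_gr))[sh]
  ref_bt <- S4Vectors::mcols(ref$exon_gr)$gene_id[sh]
  bt_map <- stats::setNames(ref$genes$biotype, ref$genes$gene_id)
  hit_bt <- biotype_category(bt_map[ref_bt])
  tx_of_hit <- tx_index[qh]
  tx_strand <- tx$strand[tx_of_hit]

  same <- tx_strand %in% c("+", "-") & tx_strand == ref_strand
  anti <- tx_strand %in% c("+", "-") & tx_strand != ref_strand
  unkn <- !(tx_strand %in% c("+", "-"))

  # precedence among annotated biotypes when several are hit
  bt_rank <- c(protein_coding = 1L, pseudogene = 2L, annotated_ncRNA = 3L,
               antisense = 4L)
  annotated_label <- rep(NA_character_, n)
  flagged <- rep(FALSE, n)
  pick_best <- function(idx_tx, labels) {
    sp <- split(labels, idx_tx)
    vapply(sp, function(l) l[which.min(bt_rank[l])], "")
  }
  if (any(same)) {
    best <- pick_best(tx_of_hit[same], hit_bt[same])
    annotated_label[as.integer(names(best))] <- best
  }
  if (any(unkn)) {
    # strand unknown: classify by location only (never antisense), flag it
    best <- pick_best(tx_of_hit[unkn], hit_bt[unkn])
    ii <- as.integer(names(best))
    fill <- is.na(annotated_label[ii])
    annotated_label[ii[fill]] <- best[fill]
    flagged[ii] <- TRUE
  }
  antisense_hit <- rep(FALSE, n)
  antisense_hit[unique(tx_of_hit[anti])] <- TRUE

  # --- novel subtype location tests ------------------------------------
  # per-exon coverage split into reference exonic / intronic / intergenic
  ov_w <- function(gr, subject) {
    hits <- GenomicRanges::findOverlaps(gr, subject, ignore.strand = TRUE)
    w <- rep(0L, length(gr))
    if (length(hits)) {
      inter <- GenomicRanges::pintersect(
        gr[S4Vectors::queryHits(hits)], subject[S4Vectors::subjectHits(hits)])
      agg <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
      w[as.integer(names(agg))] <- as.integer(agg)
    }
    w
  }
  w_total <- GenomicRanges::width(ex_gr)
  w_gene <- ov_w(ex_gr, ref$gene_space)
  w_intr <- ov_w(ex_gr, ref$intronic_space)
  w_intergenic <- w_total - w_gene

  has_intronic <- tapply(w_intr > 0L, tx_index, any)
  has_intergenic <- tapply(w_intergenic > 0L, tx_index, any)
  all_intronic <- tapply(w_intr == w_total, tx_index, all)
  all_intergenic <- tapply(w_intergenic == w_total, tx_index, all)
  as_flag <- function(t) {
    out <- rep(FALSE, n); out[as.integer(names(t))] <- as.logical(t); out
  }
  has_intronic <- as_flag(has_intronic)
  has_intergenic <- as_flag(has_intergenic)
  all_intronic <- as_flag(all_intronic)
  all_intergenic <- as_flag(all_intergenic)

  # encompassing: >= 1 reference gene whose whole span sits inside an
  # intron gap of the transcript
  encompassing <- rep(FALSE, n)
  multi <- tx$transcript_id[tx$n_exons >= 2L]
  if (length(multi)) {
    gaps <- do.call(rbind, lapply(multi, function(tid) {
      e <- ex[ex$transcript_id == tid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      data.frame(tid = tid, chrom = e$chrom[1L],
                 start = e$end[-nrow(e)] + 1L, end = e$start[-1L] - 1L,
                 stringsAsFactors = FALSE)
    }))
    gaps <- gaps[gaps$end >= gaps$start, , drop = FALSE]
    if (nrow(gaps)) {
      gap_gr <- GenomicRanges::GRanges(gaps$chrom,
                                       IRanges::IRanges(gaps$start, gaps$end))
      hits <- GenomicRanges::findOverlaps(ref$span_gr, gap_gr,
                                          type = "within",
                                          ignore.strand = TRUE)
      if (length(hits)) {
        enc_tids <- unique(gaps$tid[S4Vectors::subjectHits(hits)])
        encompassing[match(enc_tids, tx$transcript_id)] <- TRUE
      }
    }
  }

  category <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(annotated_label[i])) {
      category[i] <- annotated_label[i]
    } else if (antisense_hit[i]) {
      category[i] <- "antisense"
    } else if (encompassing[i]) {
      category[i] <- "novel_encompassing"
    } else if (all_intronic[i]) {
      category[i] <- "novel_intronic"
    } else if (has_intronic[i] && has_intergenic[i]) {
      category[i] <- "novel_interleaving"
    } else if (all_intergenic[i]) {
      category[i] <- "novel_intergenic"
    } else {
      # exons partly in intronic space, none intergenic, not fully
      # intronic (straddles an exon boundary without exonic overlap is
      # impossible; remaining edge cases are intron-boundary touches)
      category[i] <- "novel_intronic"
    }
  }
  data.frame(transcript_id = tx$transcript_id, category = category,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Classify one transcript against the reference
#'
#' Assigns exactly one category label. Precedence when several definitions
#' could match: same-strand exonic overlap with an annotated gene (label =
#' that gene's biotype; `annotated_ncRNA` covers non-coding biotypes) >
#' antisense (exclusively opposite-strand exonic overlap; requires known
#' strand) > novel encompassing (a whole reference gene inside the
#' transcript's intron space) > novel intronic (all exons in reference
#' intronic space) > novel interleaving (exons in both intronic and
#' intergenic space) > novel intergenic (all exons outside gene spans).
#' Unknown-strand transcripts overlapping reference exons are classified
#' by location only and flagged; antisense is never assigned without
#' strand.
#'
#' @param exons data.frame of the transcript's exons (`chrom`, `start`,
#'   `end`, `strand`).
#' @param ref a [reference_annotation()].
#' @return list with `category` and `flagged`.
#' @export
classify_transcript <- function(exons, ref) {
  exons <- exons[order(exons$start), , drop = FALSE]
  strand <- exons$strand[1L]
  models <- structure(list(
    transcripts = data.frame(
      transcript_id = "tx", chrom = exons$chrom[1L], strand = strand,
      start = min(exons$start), end = max(exons$end),
      n_exons = nrow(exons),
      mature_length = sum(exons$end - exons$start + 1L),
      n_samples = 1L, stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = "tx", chrom = exons$chrom,
                       strand = strand, start = exons$start,
                       end = exons$end, stringsAsFactors = FALSE),
    presence = list(tx = "s1")), class = "transcript_models")
  res <- classify_models(models, ref)
  list(category = res$category[1L], flagged = res$flagged[1L])
}

#' Build the transcript catalog
#'
#' Runs strand inference on every unknown-strand multi-exon consensus
#' model, classifies all models against the reference, and assembles the
#' catalog table (id, category, strand, mature length, span, sample
#' presence count).
#'
#' @param models a `transcript_models` object from [merge_assemblies()].
#' @param ref a [reference_annotation()].
#' @param genome named [Biostrings::DNAStringSet]; pass `NULL` to skip
#'   strand inference.
#' @return an object of class `lnc_catalog`: list with `transcripts`,
#'   `exons`, `presence`.
#' @export
build_catalog <- function(models, ref, genome = NULL) {
  tx <- models$transcripts
  ex <- models$exons
  if (anyDuplicated(tx$transcript_id))
    stopf("build_catalog: duplicate consensus transcript ids")
  if (!is.null(genome) && nrow(tx)) {
    unknown_multi <- which(!(tx$strand %in% c("+", "-")) & tx$n_exons >= 2L)
    for (i in unknown_multi) {
      s <- infer_strand(ex[ex$transcript_id == tx$transcript_id[i], ,
                           drop = FALSE], genome)
      if (s != "unknown") {
        tx$strand[i] <- s
        ex$strand[ex$transcript_id == tx$transcript_id[i]] <- s
      }
    }
    models$transcripts <- tx
    models$exons <- ex
  }
  cls <- classify_models(models, ref)
  tx$category <- cls$category[match(tx$transcript_id, cls$transcript_id)]
  tx$flagged <- cls$flagged[match(tx$transcript_id, cls$transcript_id)]
  structure(list(transcripts = tx, exons = ex, presence = models$presence),
            class = "lnc_catalog")
}

#' @export
print.lnc_catalog <- function(x, ...) {
  cat("lnc_catalog: ", nrow(x$transcripts), " transcripts\n", sep = "")
  if (nrow(x$transcripts)) {
    tb <- table(factor(x$transcripts$category, levels = CATEGORY_LEVELS))
    for (nm in names(tb)) cat(sprintf("  %-20s %d\n", nm, tb[[nm]]))
  }
  invisible(x)
}

#' Write a catalog to GTF and TSV
#'
#' @param catalog an `lnc_catalog`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "catalog.tsv")
  gtf <- file.path(dir, "catalog.gtf")
  write_tsv(catalog$transcripts, tsv)
  ex <- catalog$exons
  ex <- ex[order(ex$chrom, ex$start, ex$transcript_id), , drop = FALSE]
  cat_of <- stats::setNames(catalog$transcripts$category,
                            catalog$transcripts$transcript_id)
  strand_out <- ifelse(ex$strand %in% c("+", "-"), ex$strand, ".")
  lines <- sprintf(
    '%s\tlncskin\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; category "%s";',
    ex$chrom, ex$start, ex$end, strand_out, ex$transcript_id,
    ex$transcript_id, cat_of[ex$transcript_id])
  writeLines(lines, gtf)
  invisible(c(tsv = tsv, gtf = gtf))
}

#' Read a GTF file into an exon table
#'
#' Thin wrapper around [rtracklayer::import()] returning the exon records
#' as a data.frame with 1-based inclusive coordinates.
#'
#' @param path GTF file path.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `transcript_id` (plus `gene_biotype`/`category` when present).
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  for (extra in c("gene_biotype", "category"))
    if (extra %in% names(S4Vectors::mcols(gr)))
      df[[extra]] <- S4Vectors::mcols(gr)[[extra]]
  df
}
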