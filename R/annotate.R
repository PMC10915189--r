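## Gene annotation of significant markers (genic / flanking with bp
## distances) and hypergeometric term enrichment on local annotation
## tables.

#' Read a gene coordinate table (GFF3 or BED)
#'
#' GFF3: `gene` features, 1-based inclusive, id taken from ID=/gene_id=/
#' Name= attributes.  BED: 0-based half-open intervals converted to
#' 1-based inclusive, 4th column = id.  Format is sniffed from the file
#' extension, falling back to content.
#'
#' @param path file path.
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @return data.frame of class `GeneTable`: gene_id, chrom, start, end,
#'   strand; sorted by chromosome and start.
#' @export
readGeneTable <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.|$)", path, ignore.case = TRUE)) "gff3"
              else if (grepl("\\.bed(\\.|$)", path, ignore.case = TRUE)) "bed"
              else {
        first <- readLines(path, n = 50L)
        first <- first[!startsWith(first, "#") & nzchar(first)]
        if (length(first) && length(strsplit(first[1], "\t")[[1]]) >= 8)
          "gff3" else "bed"
      }
  }
  lines <- readLines(path)
  keepIdx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  rows <- list()
  for (i in keepIdx) {
    tok <- strsplit(lines[i], "\t")[[1]]
    if (format == "gff3") {
      if (length(tok) < 9)
        stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
      if (tolower(tok[3]) != "gene") next
      att <- tok[9]
      id <- sub(".*?(?:^|;)\\s*(?:ID|gene_id|Name)=([^;]+).*", "\\1", att,
                perl = TRUE)
      if (id == att) id <- paste0("gene_line", i)
      start <- suppressWarnings(as.numeric(tok[4]))
      end <- suppressWarnings(as.numeric(tok[5]))
      if (is.na(start) || is.na(end))
        stop("malformed GFF3 line ", i, ": non-numeric coordinates")
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = id, chrom = tok[1], start = start, end = end,
                   strand = tok[7], stringsAsFactors = FALSE)
    } else {
      if (length(tok) < 3)
        stop("malformed BED line ", i, ": expected at least 3 fields")
      start <- suppressWarnings(as.numeric(tok[2]))
      end <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(start) || is.na(end))
        stop("malformed BED line ", i, ": non-numeric coordinates")
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = if (length(tok) >= 4) tok[4]
                             else paste0("gene_line", i),
                   chrom = tok[1], start = start + 1, end = end,
                   strand = if (length(tok) >= 6) tok[6] else "*",
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no gene records found in ", path)
  gt <- do.call(rbind, rows)
  if (anyDuplicated(gt$gene_id))
    stop("duplicate gene id(s): ",
         paste(head(unique(gt$gene_id[duplicated(gt$gene_id)]), 5),
               collapse = ", "))
  if (any(gt$start > gt$end)) stop("gene with start > end")
  gt <- gt[order(gt$chrom, gt$start), ]
  rownames(gt) <- NULL
  class(gt) <- c("GeneTable", "data.frame")
  gt
}

#' Annotate SNP positions against a gene table
#'
#' A SNP inside a gene interval (1-based inclusive) is `genic` and reports
#' every overlapping gene; otherwise it is `intergenic` and reports the
#' nearest gene on each side with the unsigned bp gap to the nearer gene
#' boundary (equidistant flanks are both reported with equal distances; a
#' chromosome end yields a single flank).  SNPs on chromosomes absent from
#' the gene table are `unannotated`.  Strand is ignored for distances.
#'
#' @param snps data.frame with snp_id, chrom, bp (1-based).
#' @param genes a [readGeneTable()] result (or equivalent data.frame).
#' @return data.frame: snp_id, chrom, bp, status, genes (comma-joined
#'   "gene" or "gene (distance)" strings), nearest_distance.
#' @export
annotateSnps <- function(snps, genes) {
  stopifnot(all(c("snp_id", "chrom", "bp") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    chrom <- snps$chrom[i]; bp <- snps$bp[i]
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (!nrow(g)) {
      out[[i]] <- data.frame(snp_id = snps$snp_id[i], chrom = chrom,
                             bp = bp, status = "unannotated", genes = NA,
                             nearest_distance = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    inside <- g$start <= bp & bp <= g$end
    if (any(inside)) {
      out[[i]] <- data.frame(snp_id = snps$snp_id[i], chrom = chrom,
                             bp = bp, status = "genic",
                             genes = paste(g$gene_id[inside],
                                           collapse = ", "),
                             nearest_distance = 0,
                             stringsAsFactors = FALSE)
      next
    }
    left <- g[g$end < bp, , drop = FALSE]
    right <- g[g$start > bp, , drop = FALSE]
    ann <- character(); dists <- numeric()
    if (nrow(left)) {
      dl <- bp - max(left$end)
      gl <- left$gene_id[which.max(left$end)]
      ann <- c(ann, sprintf("%s (%d)", gl, as.integer(dl)))
      dists <- c(dists, dl)
    }
    if (nrow(right)) {
      dr <- min(right$start) - bp
      gr <- right$gene_id[which.min(right$start)]
      ann <- c(ann, sprintf("%s (%d)", gr, as.integer(dr)))
      dists <- c(dists, dr)
    }
    out[[i]] <- data.frame(snp_id = snps$snp_id[i], chrom = chrom, bp = bp,
                           status = "intergenic",
                           genes = paste(ann, collapse = ", "),
                           nearest_distance = min(dists),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Hypergeometric term enrichment
#'
#' One-sided upper-tail hypergeometric test per term: with universe size
#' N, term size K (within the universe), list size n and overlap k, p =
#' P(X >= k).  Terms with raw p < `alpha` are flagged (no multiplicity
#' adjustment for flagging, matching common DAVID-style reporting); a
#' Benjamini-Hochberg column is added for reference.
#'
#' @param geneList character vector of genes of interest (subset of
#'   `universe`).
#' @param termMap data.frame with term_id, term_name, gene_id (one row per
#'   term-gene pair).
#' @param universe character vector, the enrichment background.
#' @param alpha flagging threshold on the raw p-value (default 0.05).
#' @return data.frame sorted by p: term_id, term_name, term_size, count,
#'   p_value, p_bh, significant, genes.
#' @export
hypergeomEnrichment <- function(geneList, termMap, universe, alpha = 0.05) {
  stopifnot(all(c("term_id", "term_name", "gene_id") %in% names(termMap)))
  universe <- unique(universe)
  geneList <- unique(geneList)
  if (!length(universe)) stop("empty universe")
  if (!length(geneList)) stop("empty gene list")
  if (!all(geneList %in% universe))
    stop("gene list must be a subset of the universe")
  termMap <- termMap[termMap$gene_id %in% universe, , drop = FALSE]
  N <- length(universe); n <- length(geneList)
  terms <- unique(termMap[, c("term_id", "term_name")])
  rows <- lapply(seq_len(nrow(terms)), function(t) {
    tg <- unique(termMap$gene_id[termMap$term_id == terms$term_id[t]])
    K <- length(tg)
    hit <- intersect(geneList, tg)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[t], term_name = terms$term_name[t],
               term_size = K, count = k, p_value = p,
               genes = paste(sort(hit), collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out[, c("term_id", "term_name", "term_size", "count", "p_value",
          "p_bh", "significant", "genes")]
}
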