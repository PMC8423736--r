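# Readers and writers for the pipeline's standard artifacts. All tables are
# tab-delimited UTF-8 with a mandatory header row; every writer here has a
# paired reader that parses its output back to an equal object.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write an OTU abundance table
#'
#' Rows are OTUs, columns are hosts (common amplicon convention); the first
#' column carries the OTU id. Values are printed with 15 significant digits so
#' a write/read round trip preserves them past 12 digits.
#'
#' @param abundance OTUs x hosts numeric matrix with dimnames.
#' @param path Output TSV path.
#' @export
write_otu_table <- function(abundance, path) {
  df <- data.frame(otu_id = rownames(abundance),
                   signif(abundance, 15), check.names = FALSE)
  write_tsv(df, path)
}

#' Read an OTU abundance table, keeping the top-k OTUs per kingdom
#'
#' Parses a TSV with OTU rows and host columns (a transposed table is
#' auto-detected when its column ids match the taxonomy's OTU ids) and
#' restricts it to the \code{top_k} most abundant OTUs per kingdom, ranked by
#' total abundance across hosts. Ties break by OTU id lexicographic order.
#' Output row order is bacteria first, then fungi, each by descending total
#' abundance.
#'
#' @param path TSV path; first column = OTU id.
#' @param taxonomy Taxonomy data.frame (otu_id, kingdom, ...); required when
#'   \code{top_k} is finite.
#' @param top_k OTUs to keep per kingdom (default 100); \code{Inf} keeps all.
#' @return OTUs x hosts numeric matrix.
#' @export
read_otu_table <- function(path, taxonomy = NULL, top_k = 100) {
  df <- read_tsv(path)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- ids
  if (!is.null(taxonomy) &&
      !any(ids %in% taxonomy$otu_id) &&
      any(colnames(mat) %in% taxonomy$otu_id)) {
    mat <- t(mat)  # transposed input: columns were OTUs
  }
  if (any(mat < 0, na.rm = TRUE)) stop("format error: negative abundances")
  if (is.infinite(top_k) || is.null(taxonomy)) return(mat)
  kingdom <- taxonomy$kingdom[match(rownames(mat), taxonomy$otu_id)]
  keep <- character(0)
  for (kd in c("bacteria", "fungi")) {
    in_k <- rownames(mat)[!is.na(kingdom) & kingdom == kd]
    if (length(in_k) == 0) next
    tot <- rowSums(mat[in_k, , drop = FALSE])
    ord <- in_k[order(-tot, in_k)]
    if (length(ord) < top_k) {
      warning(sprintf("kingdom %s has %d OTUs (< top_k = %s); keeping all",
                      kd, length(ord), format(top_k)))
    }
    keep <- c(keep, utils::head(ord, top_k))
  }
  mat[keep, , drop = FALSE]
}

#' Write genotypes as a 0/1 TSV
#'
#' Rows are hosts, columns SNPs; missing calls are printed as \code{NA}.
#' @param genotypes Hosts x SNPs matrix of 0/1/NA with dimnames.
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(host_id = rownames(genotypes), genotypes, check.names = FALSE)
  write_tsv(df, path)
}

#' Write genotypes as a minimal VCF
#'
#' Homozygous-diploid GT records (0 -> \code{0/0}, 1 -> \code{1/1}, missing ->
#' \code{./.}) on a single pseudo-chromosome, VCFv4.2, GT-only FORMAT.
#'
#' @inheritParams write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  hosts <- rownames(genotypes)
  snps <- colnames(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hosts), collapse = "\t")
  ), con)
  gt <- matrix("./.", ncol(genotypes), nrow(genotypes))
  tg <- t(genotypes)
  gt[!is.na(tg) & tg == 0] <- "0/0"
  gt[!is.na(tg) & tg == 1] <- "1/1"
  lines <- paste("1", seq_along(snps), snps, "A", "T", ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a genotype matrix from VCF or 0/1 TSV
#'
#' VCF calls are mapped \code{0/0 -> 0}, \code{1/1 -> 1}, anything else
#' (heterozygous, missing) to \code{NA}. When an abundance matrix is supplied
#' the hosts are aligned by intersection of ids, and dropped hosts reported.
#'
#' @param path VCF (\code{.vcf}/\code{.vcf.gz}) or TSV path.
#' @param abundance Optional OTUs x hosts matrix to align hosts against.
#' @return Hosts x SNPs matrix of 0/1/NA; attribute \code{dropped_hosts}
#'   lists genotyped hosts without abundance data.
#' @export
read_genotypes <- function(path, abundance = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    G <- matrix(NA_real_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
    tg <- t(gt)
    G[tg %in% c("0/0", "0|0")] <- 0
    G[tg %in% c("1/1", "1|1")] <- 1
  } else {
    df <- read_tsv(path)
    G <- as.matrix(df[, -1, drop = FALSE])
    mode(G) <- "numeric"
    rownames(G) <- as.character(df[[1]])
  }
  if (!is.null(abundance)) {
    common <- intersect(colnames(abundance), rownames(G))
    if (length(common) == 0) stop("alignment error: no overlapping hosts")
    dropped <- setdiff(rownames(G), common)
    G <- G[common, , drop = FALSE]
    attr(G, "dropped_hosts") <- dropped
  }
  G
}

#' Read a taxonomy table
#' @param path TSV with columns otu_id, kingdom, phylum, class.
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  tx <- read_tsv(path)
  need <- c("otu_id", "kingdom")
  if (!all(need %in% names(tx))) stop("taxonomy needs otu_id and kingdom columns")
  tx
}

#' Export an interaction network
#'
#' GraphML carries node attributes (otu_id, kingdom, class, hub flag when
#' present) and the edge weight; the edge-list TSV has columns source, target,
#' weight, directed.
#'
#' @param net An igraph network from [build_network()].
#' @param path Output file.
#' @param format \code{"graphml"} or \code{"edgelist-tsv"}.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = TRUE)
    w <- igraph::E(net)$weight
    df <- data.frame(source = el[, 1], target = el[, 2],
                     weight = if (is.null(w)) rep(1, nrow(el)) else w,
                     directed = rep(igraph::is_directed(net), nrow(el)))
    write_tsv(df, path)
  }
  invisible(path)
}

#' Read a GraphML network back
#' @param path GraphML file written by [write_network()].
#' @return igraph object.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
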