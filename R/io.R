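# Readers/writers for the standard interchange formats: VCF and TSV
# genotypes, BED intervals (0-based half-open, converted on read), GWAS
# summary TSV, GTF annotation subset, and the association output table.

#' Read genotypes from a VCF file
#'
#' Uses hard genotype calls (GT) or, when present and requested, imputed
#' dosages (DS). Requires the `vcfR` package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param field `"GT"` (default) or `"DS"`.
#' @return A `genotype_panel`.
#' @export
read_genotype_vcf <- function(path, field = c("GT", "DS")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  field <- match.arg(field)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  if (field == "GT") {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    D <- apply(gt, 2, count_alt)
  } else {
    D <- apply(vcfR::extract.gt(v, element = "DS"), 2, as.numeric)
  }
  D <- t(D) # individuals x SNPs
  colnames(D) <- ids
  map <- validate_snp_map(data.frame(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_ref = fix$REF, allele_alt = fix$ALT, stringsAsFactors = FALSE))
  structure(list(dosages = D, snp_map = map,
                 maf = pmin(colMeans(D, na.rm = TRUE) / 2,
                            1 - colMeans(D, na.rm = TRUE) / 2)),
            class = "genotype_panel")
}

#' Write / read a genotype panel as plain TSV
#'
#' The matrix dialect is rows = individuals (first column `individual_id`),
#' columns = snp_ids; the SNP map travels in a sibling file
#' `<path>.map.tsv`.
#'
#' @param panel A `genotype_panel`.
#' @param path Output TSV path.
#' @export
write_genotype_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  dt <- data.table::data.table(individual_id = rownames(panel$dosages))
  dt <- cbind(dt, data.table::as.data.table(panel$dosages))
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(panel$snp_map, paste0(path, ".map.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt$individual_id
  D <- as.matrix(dt[, -1])
  rownames(D) <- ids
  map <- validate_snp_map(as.data.frame(
    data.table::fread(paste0(path, ".map.tsv"), sep = "\t",
                      colClasses = list(character = c("chrom", "allele_ref",
                                                      "allele_alt")))))
  structure(list(dosages = D, snp_map = map,
                 maf = pmin(colMeans(D) / 2, 1 - colMeans(D) / 2)),
            class = "genotype_panel")
}

#' Read a BED interval file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention (start + 1, end unchanged). Uses
#' `rtracklayer` when available, else a minimal three-column parser.
#'
#' @param path BED path.
#' @return data.frame: chrom, start, end (1-based inclusive), name if
#'   present.
#' @export
read_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    df <- as.data.frame(rtracklayer::import(path, format = "BED"))
    out <- data.frame(chrom = as.character(df$seqnames), start = df$start,
                      end = df$end, stringsAsFactors = FALSE)
    if (!is.null(df$name)) out$name <- df$name
    return(out)
  }
  dt <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(dt[[1]]), start = dt[[2]] + 1L,
                    end = dt[[3]], stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) out$name <- dt[[4]]
  out
}

#' Write / read GWAS summary statistics TSV
#'
#' Columns: snp_id, chrom, pos, a_ref, a_alt, beta, se, z, n. On read,
#' a missing z is reconstructed as beta/se and a supplied z is checked
#' against beta/se.
#'
#' @param gwas GWAS summary data.frame.
#' @param path TSV path.
#' @export
write_gwas_tsv <- function(gwas, path) {
  need <- c("snp_id", "chrom", "pos", "a_ref", "a_alt", "beta", "se", "z", "n")
  stopifnot(all(need %in% names(gwas)))
  data.table::fwrite(gwas[need], path, sep = "\t")
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  g <- as.data.frame(data.table::fread(path, sep = "\t",
                                       colClasses = list(character = c(
                                         "snp_id", "chrom", "a_ref", "a_alt"))))
  if (!"z" %in% names(g)) g$z <- g$beta / g$se
  bad <- abs(g$z - g$beta / g$se) >= 1e-6
  if (any(bad, na.rm = TRUE)) {
    stop(sum(bad, na.rm = TRUE), " row(s) with z inconsistent with beta/se")
  }
  if (any(g$n <= 0)) stop("n must be positive")
  g
}

#' Read a transcriptome annotation from a GTF subset
#'
#' Consumes gene and transcript feature lines only. TSS is the start for
#' plus-strand features and the end for minus-strand features. Uses
#' `rtracklayer` when available, else a minimal attribute parser.
#'
#' @param path GTF path.
#' @return A `tx_annotation`.
#' @export
read_gtf_annotation <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    df <- as.data.frame(rtracklayer::import(path, format = "GTF"))
    d <- data.frame(type = as.character(df$type),
                    chrom = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    gene_id = df$gene_id,
                    transcript_id = if (!is.null(df$transcript_id))
                      df$transcript_id else NA_character_,
                    stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                             comment.char = "#", stringsAsFactors = FALSE)
    get_attr <- function(a, key) {
      m <- regmatches(a, regexpr(paste0(key, ' "[^"]+"'), a))
      ifelse(lengths(regmatches(a, gregexpr(paste0(key, ' "'), a))) > 0,
             sub(paste0(key, ' "([^"]+)"'), "\\1", m), NA_character_)
    }
    d <- data.frame(type = raw[[3]], chrom = as.character(raw[[1]]),
                    start = raw[[4]], end = raw[[5]], strand = raw[[7]],
                    gene_id = get_attr(raw[[9]], "gene_id"),
                    transcript_id = get_attr(raw[[9]], "transcript_id"),
                    stringsAsFactors = FALSE)
  }
  gd <- d[d$type == "gene", , drop = FALSE]
  td <- d[d$type == "transcript", , drop = FALSE]
  if (!nrow(gd) || !nrow(td)) stop("GTF must contain gene and transcript lines")
  if (!all(td$gene_id %in% gd$gene_id)) {
    stop("transcript(s) reference unknown gene_id")
  }
  genes <- data.frame(gene_id = gd$gene_id, chrom = gd$chrom,
                      strand = gd$strand, gene_start = as.integer(gd$start),
                      gene_end = as.integer(gd$end),
                      tss = as.integer(ifelse(gd$strand == "+", gd$start, gd$end)),
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = td$transcript_id,
                            gene_id = td$gene_id, chrom = td$chrom,
                            strand = td$strand,
                            tss = as.integer(ifelse(td$strand == "+", td$start,
                                                    td$end)),
                            stringsAsFactors = FALSE)
  structure(list(genes = genes, transcripts = transcripts),
            class = "tx_annotation")
}

#' Write an association output table
#'
#' One row per feature: feature_id, gene_id, level, z, p_raw, p_screen,
#' p_fwer, p_perm, chisq.
#'
#' @param records Adjusted association data.frame.
#' @param path TSV path.
#' @export
write_assoc_tsv <- function(records, path) {
  out <- data.frame(
    feature_id = records$feature_id, gene_id = records$gene_id,
    level = records$level, z = records$z_assoc, p_raw = records$p_raw,
    p_screen = records$p_gene_screen, p_fwer = records$p_fwer_within,
    p_perm = if ("p_perm" %in% names(records)) records$p_perm else NA_real_,
    chisq = records$chisq, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
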