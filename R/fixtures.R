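extdata <- function(...) {
  system.file("extdata", ..., package = "iciomics", mustWork = TRUE)
}

#' Grantham amino-acid distance matrix
#'
#' 20x20 symmetric matrix of Grantham distances computed from the
#' composition/polarity/volume formula (weights 1.833 / 0.1018 / 0.000399,
#' scale 50.723) and rounded to integers; the diagonal is zero. Used for
#' HLA evolutionary divergence.
#'
#' @param path TSV fixture path (defaults to the shipped table)
#' @return numeric matrix with amino-acid dimnames
#' @export
grantham_matrix <- function(path = extdata("grantham_distance.tsv")) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  stopifnot(identical(rownames(m), colnames(m)),
            isTRUE(all.equal(m, t(m))), all(diag(m) == 0))
  m
}

#' HLA-B supertype membership table
#'
#' Editable allele -> supertype (B27/B44/B62) table following the standard
#' functional classification of HLA-B peptide-binding specificities.
#' Alleles absent from the table carry no supertype.
#'
#' @param path TSV fixture path
#' @return data.frame with `allele` and `supertype`
#' @export
hla_supertype_table <- function(path = extdata("hla_b_supertypes.tsv")) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Expression signature gene sets
#'
#' Editable marker lists: interferon-gamma response, immunosuppression,
#' lymphocyte markers, and HLA class I genes. One symbol per line.
#'
#' @param dir directory holding the `signature_*.txt` fixtures
#' @return named list of character vectors
#' @export
signature_sets <- function(dir = dirname(extdata("signature_ifng.txt"))) {
  read_list <- function(f) {
    x <- readLines(file.path(dir, f))
    x <- x[nzchar(x)]
    if (anyDuplicated(x)) stop("duplicate symbols in ", f)
    x
  }
  sets <- list(ifng_signature = read_list("signature_ifng.txt"),
               immunosuppression_signature = read_list("signature_ims.txt"),
               lymphocyte_markers = read_list("signature_lymphocyte.txt"),
               hla_class1_genes = read_list("signature_hla_class1.txt"))
  if (any(lengths(sets) == 0)) stop("empty signature gene list")
  sets
}

#' Gene alteration rules
#'
#' Maps each flagged gene to its qualifying alteration class:
#' `lof` (frameshift/nonsense/splice variant or overlapping deletion),
#' `nonsyn` (any nonsynonymous SNV), or `amp` (copy number >= 4). Every
#' gene must have coordinates in the gene-region fixture so copy-number
#' rules can be evaluated.
#'
#' @param path rules TSV fixture path
#' @param regions named `GRanges` of gene coordinates
#' @return data.frame with `gene` and `class`
#' @export
resistance_rules <- function(path = extdata("resistance_rules.tsv"),
                             regions = gene_regions()) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (any(!tab$class %in% c("lof", "nonsyn", "amp"))) {
    stop("unknown alteration class in rules file")
  }
  unknown <- setdiff(tab$gene, names(regions))
  if (length(unknown)) {
    stop("rules name gene(s) without coordinates: ",
         paste(unknown, collapse = ", "))
  }
  tab
}

#' Gene coordinate fixture (GRCh38, approximate gene bodies)
#' @param path BED fixture path
#' @return named `GRanges`
#' @export
gene_regions <- function(path = extdata("gene_regions_grch38.bed")) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name"))
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start + 1L, tab$end))
  names(gr) <- tab$name
  gr
}

#' chr6p21.3 locus (GRCh38 extended MHC region)
#' @param path BED fixture path
#' @return `GRanges` of the HLA class I-containing locus
#' @export
chr6p21_region <- function(path = extdata("chr6p21_3_grch38.bed")) {
  read_intervals(path)
}

#' Synthetic HLA allele protein sequences
#'
#' Frozen random peptide-binding-domain stand-ins (50 aa per allele) for
#' the class I alleles used by the synthetic cohort generator. These are
#' synthetic sequences, not IMGT/HLA data.
#'
#' @param path TSV fixture path
#' @return named character vector, allele -> sequence
#' @export
synthetic_hla_sequences <- function(path = extdata("synthetic_hla_sequences.tsv")) {
  read_hla_sequences(path)
}

#' Load all shipped reference fixtures at once
#' @return list with `grantham`, `supertypes`, `signatures`, `rules`,
#'   `gene_regions`, `chr6p21`
#' @export
ici_fixtures <- function() {
  regions <- gene_regions()
  chr6 <- chr6p21_region()
  list(grantham = grantham_matrix(),
       supertypes = hla_supertype_table(),
       signatures = signature_sets(),
       rules = resistance_rules(regions = regions),
       gene_regions = regions,
       gene_regions_frame = regions_frame(regions),
       chr6p21 = chr6,
       chr6p21_frame = data.frame(
         chrom = as.character(GenomicRanges::seqnames(chr6))[1],
         start = GenomicRanges::start(chr6)[1],
         end = GenomicRanges::end(chr6)[1]))
}
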