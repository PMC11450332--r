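#' Recode a pair of minor-allele dosages into a composite dosage
#'
#' The composite-SNP construction sums the minor-allele dosages of two
#' constituent SNPs (0-4) and recodes the sum to a pseudo-genotype: sums 0
#' or 1 map to 0, a sum of 2 maps to 1, and sums 3 or 4 map to 2. A missing
#' constituent dosage yields a missing composite dosage.
#'
#' @param dosage_a,dosage_b integer vectors with values in `{0, 1, 2}` or
#'   `NA`; recycled to a common length.
#' @return integer vector of composite dosages in `{0, 1, 2, NA}`.
#' @examples
#' recode_pair(c(0, 1, 2), c(0, 1, 2))  # 0, 1, 2
#' @export
recode_pair <- function(dosage_a, dosage_b) {
  check_dosage <- function(d, name) {
    bad <- !is.na(d) & !(d %in% c(0, 1, 2))
    if (any(bad)) {
      abort(sprintf("`%s` contains dosages outside {0, 1, 2}", name))
    }
  }
  check_dosage(dosage_a, "dosage_a")
  check_dosage(dosage_b, "dosage_b")
  s <- dosage_a + dosage_b
  out <- rep(NA_integer_, length(s))
  out[!is.na(s) & s <= 1] <- 0L
  out[!is.na(s) & s == 2] <- 1L
  out[!is.na(s) & s >= 3] <- 2L
  out
}

#' Build composite variants from all SNP pairs in scope
#'
#' Pairs candidate SNPs and recodes each pair's summed minor-allele dosage
#' with [recode_pair()], yielding one composite variant per unordered pair.
#' Composites carry synthetic placement metadata (chromosome `"0"`, ordinal
#' positions) since a pair spans two loci, and their coded-allele frequency
#' is definitional — it is not re-aligned to be the minor allele.
#'
#' @param g a [geno_matrix()] of single SNPs (gene labels required for the
#'   gene-restricted scopes).
#' @param pairing_scope `"all_pairs"` (default), `"between_genes"` (only
#'   pairs whose constituents are in different genes) or `"within_genes"`.
#' @return A [geno_matrix()] of composite variants; its `variants` tibble
#'   carries `constituent_1`, `constituent_2` and the constituent genes,
#'   and doubles as the composite manifest.
#' @export
build_composites <- function(g,
                             pairing_scope = c("all_pairs", "between_genes",
                                               "within_genes")) {
  pairing_scope <- match.arg(pairing_scope)
  stopifnot(inherits(g, "geno_matrix"))
  m <- nrow(g$variants)
  if (m < 2L) {
    warn("fewer than 2 variants: no composites to build")
    return(empty_composites(g))
  }
  ord <- order(g$variants$id)
  pr <- utils::combn(ord, 2L)
  gene <- g$variants$gene
  if (pairing_scope == "between_genes") {
    keep <- gene[pr[1L, ]] != gene[pr[2L, ]]
    pr <- pr[, keep, drop = FALSE]
  } else if (pairing_scope == "within_genes") {
    keep <- gene[pr[1L, ]] == gene[pr[2L, ]]
    pr <- pr[, keep, drop = FALSE]
  }
  if (ncol(pr) == 0L) {
    warn(sprintf("no SNP pairs in scope '%s'", pairing_scope))
    return(empty_composites(g))
  }
  id1 <- g$variants$id[pr[1L, ]]
  id2 <- g$variants$id[pr[2L, ]]
  dos <- matrix(NA_integer_, nrow = length(g$ids), ncol = ncol(pr))
  for (j in seq_len(ncol(pr))) {
    dos[, j] <- recode_pair(g$dosages[, pr[1L, j]], g$dosages[, pr[2L, j]])
  }
  variants <- tibble::tibble(
    id = paste0(id1, "_x_", id2),
    gene = paste0(gene[pr[1L, ]], ":", gene[pr[2L, ]]),
    chrom = "0",
    pos = seq_len(ncol(pr)),
    a1 = "C",
    a2 = "N",
    maf = colMeans(dos, na.rm = TRUE) / 2,
    constituent_1 = id1,
    constituent_2 = id2,
    gene_1 = gene[pr[1L, ]],
    gene_2 = gene[pr[2L, ]]
  )
  geno_matrix(dos, variants, ids = g$ids)
}

empty_composites <- function(g) {
  geno_matrix(
    matrix(integer(), nrow = length(g$ids), ncol = 0L),
    tibble::tibble(
      id = character(), gene = character(), chrom = character(),
      pos = integer(), a1 = character(), a2 = character(), maf = numeric(),
      constituent_1 = character(), constituent_2 = character(),
      gene_1 = character(), gene_2 = character()
    ),
    ids = g$ids
  )
}

#' Write composite variants as a PLINK triplet plus manifest
#'
#' The composite coding is definitional, so files written here should be
#' read back with `read_plink(prefix, align_minor = FALSE)`: a composite's
#' coded-allele frequency may legitimately exceed 0.5.
#'
#' @param composites a [geno_matrix()] from [build_composites()].
#' @param prefix output path prefix; writes the bed/bim/fam triplet and a
#'   `<prefix>.manifest.tsv` (composite id, constituents, genes).
#' @export
write_composite_plink <- function(composites, prefix) {
  stopifnot(inherits(composites, "geno_matrix"))
  if (nrow(composites$variants) == 0L) {
    abort("no composite variants to write")
  }
  if (anyDuplicated(composites$variants$id)) {
    abort("composite variant ids collide")
  }
  write_plink(composites, prefix)
  manifest <- dplyr::select(
    composites$variants,
    dplyr::any_of(c("id", "constituent_1", "constituent_2",
                    "gene_1", "gene_2", "maf"))
  )
  readr::write_tsv(manifest, paste0(prefix, ".manifest.tsv"))
  invisible(prefix)
}
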