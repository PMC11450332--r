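#' Genotype container
#'
#' A light container for an individuals-by-variants minor-allele dosage
#' matrix plus variant metadata. Dosages count copies of the coded (minor)
#' allele: 0, 1, 2 or `NA` for missing.
#'
#' @param dosages integer matrix, individuals in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`. Row names are individual ids, column names
#'   variant ids (supplied separately if absent).
#' @param variants tibble with one row per variant: `id`, `gene`, `chrom`,
#'   `pos`, `a1` (coded allele), `a2`, `maf` (recomputed if missing).
#' @param ids character vector of individual ids (defaults to row names).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants, ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dosages)))
  ids <- as.character(ids)
  variants <- tibble::as_tibble(variants)
  stopifnot(nrow(variants) == ncol(dosages))
  if (anyDuplicated(variants$id)) abort("variant ids must be unique")
  if (anyDuplicated(ids)) abort("individual ids must be unique")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosages must be in {0, 1, 2} or NA")
  }
  rownames(dosages) <- ids
  colnames(dosages) <- variants$id
  if (!"maf" %in% names(variants)) {
    variants$maf <- coded_allele_freq(dosages)
  }
  structure(
    list(dosages = dosages, variants = variants, ids = ids),
    class = "geno_matrix"
  )
}

#' @method print geno_matrix
#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d individuals x %d variants (%d genes)\n",
    length(x$ids), nrow(x$variants), dplyr::n_distinct(x$variants$gene)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

coded_allele_freq <- function(dosages) {
  colMeans(dosages, na.rm = TRUE) / 2
}

# 2-bit PLINK bed codes (variant-major): for the coded allele a1,
# 0b00 = two copies of a1 (dosage 2), 0b01 = missing, 0b10 = het,
# 0b11 = zero copies (dosage 0). Four individuals per byte, first
# individual in the two lowest-order bits.
.bed_code_from_dosage <- c(`2` = 0L, `1` = 2L, `0` = 3L)

.bed_decode_table <- local({
  # 256 x 4 matrix: dosage of a1 per 2-bit field of each byte value
  per2bit <- c(2L, NA_integer_, 1L, 0L)
  m <- matrix(NA_integer_, 256L, 4L)
  for (b in 0:255) {
    for (k in 0:3) {
      m[b + 1L, k + 1L] <- per2bit[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
    }
  }
  m
})

#' Read a PLINK bed/bim/fam triplet
#'
#' Decodes variant-major 2-bit genotypes into minor-allele dosages. By
#' default each variant is aligned so that the coded allele is the minor
#' allele in-sample: where the bim coded allele (a1) has frequency > 0.5
#' the dosages are flipped (0 <-> 2) and the allele labels swapped.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param align_minor flip variants whose coded allele is major in-sample
#'   (default `TRUE`). Set `FALSE` for composite-variant files, whose coding
#'   is definitional rather than frequency-based.
#' @return A [geno_matrix()].
#' @export
read_plink <- function(prefix, align_minor = TRUE) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(paste0("missing PLINK file: ", f))
  }
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  ids <- fam_df[[2L]]
  n <- nrow(fam_df)
  if (file.size(bim) == 0L) {
    bim_df <- data.frame(
      chrom = character(), id = character(), cm = numeric(),
      pos = integer(), a1 = character(), a2 = character()
    )
  } else {
    bim_df <- utils::read.table(
      bim, header = FALSE,
      col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
      colClasses = c("character", "character", "numeric", "integer",
                     "character", "character")
    )
  }
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    abort("not a PLINK bed file (bad magic bytes)")
  }
  if (raw[3L] != as.raw(0x01)) {
    abort("only variant-major bed files are supported")
  }
  bpv <- ceiling(n / 4)        # bytes per variant
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * m) {
    abort(sprintf(
      "bed payload has %d bytes; expected %d for %d individuals x %d variants",
      length(payload), bpv * m, n, m
    ))
  }
  if (m == 0L) {
    dos <- matrix(integer(), n, 0L)
  } else {
    bytes <- matrix(as.integer(payload), nrow = bpv, ncol = m)
    dos <- matrix(NA_integer_, n, m)
    for (k in 0:3) {
      rows <- seq.int(1L + k, by = 4L, length.out = bpv)
      rows <- rows[rows <= n]
      if (!length(rows)) next
      bidx <- ((rows - 1L) %/% 4L) + 1L
      dos[rows, ] <- .bed_decode_table[bytes[bidx, , drop = FALSE] + 1L,
                                       k + 1L]
    }
  }
  variants <- tibble::tibble(
    id = bim_df$id,
    gene = NA_character_,
    chrom = bim_df$chrom,
    pos = bim_df$pos,
    a1 = bim_df$a1,
    a2 = bim_df$a2
  )
  if (align_minor && m > 0L) {
    freq <- coded_allele_freq(`colnames<-`(dos, variants$id))
    flip <- !is.na(freq) & freq > 0.5
    if (any(flip)) {
      dos[, flip] <- 2L - dos[, flip]
      tmp <- variants$a1[flip]
      variants$a1[flip] <- variants$a2[flip]
      variants$a2[flip] <- tmp
    }
  }
  variants$maf <- if (m > 0L) {
    unname(coded_allele_freq(dos))
  } else numeric()
  g <- geno_matrix(dos, variants, ids = ids)
  g$fam <- tibble::tibble(
    family_id = fam_df[[1L]], id = ids,
    father = fam_df[[3L]], mother = fam_df[[4L]],
    sex = fam_df[[5L]], phenotype = fam_df[[6L]]
  )
  g
}

#' Write a PLINK bed/bim/fam triplet
#'
#' @param g a [geno_matrix()].
#' @param prefix output path prefix.
#' @param family_ids optional family ids for the fam file (defaults to the
#'   individual id, i.e. unrelated singletons).
#' @param sex optional 1/2 sex codes for the fam file.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, family_ids = NULL, sex = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- length(g$ids)
  m <- nrow(g$variants)
  fam <- data.frame(
    fid = family_ids %||% g$ids,
    iid = g$ids,
    pat = 0L, mat = 0L,
    sex = sex %||% rep(0L, n),
    phe = -9L
  )
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (m > 0L) {
    bim <- data.frame(
      chrom = if ("chrom" %in% names(g$variants)) g$variants$chrom
              else rep("0", m),
      id = g$variants$id,
      cm = 0,
      pos = if ("pos" %in% names(g$variants)) g$variants$pos else seq_len(m),
      a1 = g$variants$a1,
      a2 = g$variants$a2
    )
    utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  } else {
    writeLines(character(0), paste0(prefix, ".bim"))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0L) {
    bpv <- ceiling(n / 4)
    pad <- bpv * 4L - n
    out <- raw(bpv * m)
    code <- matrix(1L, nrow = n + pad, ncol = m)  # 0b01 = missing
    d <- g$dosages
    for (dv in c(0L, 1L, 2L)) {
      code[seq_len(n), ][!is.na(d) & d == dv] <-
        .bed_code_from_dosage[[as.character(dv)]]
    }
    code[seq_len(n), ][is.na(d)] <- 1L
    if (pad > 0L) code[(n + 1L):(n + pad), ] <- 0L  # pad bits zero
    shift <- rep(c(1L, 4L, 16L, 64L), length.out = n + pad)
    byte_of <- rep(seq_len(bpv), each = 4L)
    for (j in seq_len(m)) {
      v <- code[, j] * shift
      out[(j - 1L) * bpv + seq_len(bpv)] <-
        as.raw(rowsum(v, byte_of)[, 1L])
    }
    writeBin(out, con)
  }
  invisible(prefix)
}

#' Write a cohort phenotype table as TSV
#'
#' Repeated BMI measurements are serialized into a single `bmi_measures`
#' column as `age:bmi` pairs separated by `;` (e.g. `"76.2:24.1;80.5:26"`).
#'
#' @param cohort cohort tibble (see [simulate_cohort()]).
#' @param path output file.
#' @export
write_phenotypes <- function(cohort, path) {
  out <- cohort
  if (is.list(out$bmi_measures)) {
    out$bmi_measures <- purrr::map_chr(out$bmi_measures, function(mm) {
      if (is.null(mm) || nrow(mm) == 0L) return("")
      paste(sprintf("%.6g:%.6g", mm$age, mm$bmi), collapse = ";")
    })
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a cohort phenotype TSV written by [write_phenotypes()]
#'
#' @param path input file.
#' @return tibble with `bmi_measures` re-nested as a list-column of
#'   `(age, bmi)` tibbles.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in intersect(c("id", "family_id", "bmi_measures"), names(ph))) {
    ph[[col]] <- as.character(ph[[col]])
  }
  ph$bmi_measures <- lapply(ph$bmi_measures, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(bmi_frame(numeric(), numeric()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    bmi_frame(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  })
  ph
}
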