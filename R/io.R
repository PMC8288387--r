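#' Parental-diagnostic SNP panel
#'
#' Ordered biallelic SNPs at which the two parental genomes (NPB = *japonica*
#' cv. Nipponbare, IND = *indica* cv. 93-11) are homozygous for different
#' alleles, so that every read can be assigned to a subgenome of origin.
#'
#' @param chrom chromosome names.
#' @param pos 0-based positions (VCF positions are converted on read).
#' @param npb_allele,ind_allele the diagnostic alleles of the two parents.
#' @return object of class `snp_panel` (a data.frame sorted by chrom, pos).
#' @export
snp_panel <- function(chrom, pos, npb_allele, ind_allele) {
  if (any(npb_allele == ind_allele)) stop("diagnostic alleles must differ")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   npb_allele = as.character(npb_allele),
                   ind_allele = as.character(ind_allele),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Read a parental-diagnostic SNP panel from a VCF
#'
#' Retains only biallelic records at which both parental samples are
#' homozygous for different alleles.
#'
#' @param path VCF file (plain or bgzipped).
#' @param npb_sample,ind_sample names of the two parental sample columns.
#' @return a [snp_panel()].
#' @export
read_snp_panel <- function(path, npb_sample = "NPB", ind_sample = "9311") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  missing <- setdiff(c(npb_sample, ind_sample), colnames(gt))
  if (length(missing) > 0)
    stop("parental sample column(s) missing from VCF: ",
         paste(missing, collapse = ", "))
  norm <- function(g) gsub("|", "/", g, fixed = TRUE)
  gn <- norm(gt[, npb_sample]); gi <- norm(gt[, ind_sample])
  biallelic <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE)
  hom <- function(g) !is.na(g) & g %in% c("0/0", "1/1")
  keep <- biallelic & hom(gn) & hom(gi) & gn != gi
  if (!any(keep)) stop("no diagnostic SNPs found in ", path)
  ref <- fix[keep, "REF"]; alt <- fix[keep, "ALT"]
  npb_is_ref <- gn[keep] == "0/0"
  snp_panel(chrom = fix[keep, "CHROM"],
            pos = as.integer(fix[keep, "POS"]) - 1L,
            npb_allele = ifelse(npb_is_ref, ref, alt),
            ind_allele = ifelse(npb_is_ref, alt, ref))
}

#' Per-individual parental allele depths
#'
#' @param reads_npb,reads_ind integer matrices (individuals x SNPs) of read
#'   counts supporting the NPB and 93-11 allele; rownames are individual ids.
#' @param panel the [snp_panel()] the columns are aligned to.
#' @return object of class `allele_depth_matrix`.
#' @export
allele_depth_matrix <- function(reads_npb, reads_ind, panel) {
  stopifnot(identical(dim(reads_npb), dim(reads_ind)),
            ncol(reads_npb) == nrow(panel))
  if (any(reads_npb < 0) || any(reads_ind < 0)) stop("read counts must be >= 0")
  ids <- rownames(reads_npb)
  if (is.null(ids) || anyDuplicated(ids))
    stop("individual ids (rownames) must be present and unique")
  structure(list(npb = reads_npb, ind = reads_ind, panel = panel),
            class = "allele_depth_matrix")
}

#' @export
print.allele_depth_matrix <- function(x, ...) {
  cat(sprintf("allele_depth_matrix: %d individuals x %d SNPs (mean depth %.2f)\n",
              nrow(x$npb), ncol(x$npb), mean(x$npb + x$ind)))
  invisible(x)
}

#' Read parental allele depths aligned to a SNP panel
#'
#' Accepts either a VCF whose samples carry an `AD` FORMAT field (ref,alt
#' order, reoriented per SNP to NPB/93-11 using the panel alleles), or a TSV
#' with columns `individual`, `chrom`, `pos` (0-based), `reads_npb`,
#' `reads_ind`.  Cells absent from the input are (0, 0).
#'
#' @param path input file; `.vcf`/`.vcf.gz` dispatches to the VCF reader.
#' @param panel a [snp_panel()].
#' @param individuals optional character vector fixing the individual set and
#'   order (TSV input only); defaults to the individuals seen in the file.
#' @return an [allele_depth_matrix()].
#' @export
read_allele_depths <- function(path, panel, individuals = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    .read_allele_depths_vcf(path, panel)
  } else {
    .read_allele_depths_tsv(path, panel, individuals)
  }
}

.read_allele_depths_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  if (!is.null(ad) && is.null(dim(ad))) ad <- t(as.matrix(ad))
  if (is.null(ad) || all(is.na(ad))) stop("AD field missing from VCF ", path)
  key <- paste(fix[, "CHROM"], as.integer(fix[, "POS"]) - 1L)
  pkey <- paste(panel$chrom, panel$pos)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " VCF record(s) not in panel; skipped")
  }
  ids <- colnames(ad)
  n <- length(ids); m <- nrow(panel)
  npb <- matrix(0L, n, m, dimnames = list(ids, NULL))
  ind <- matrix(0L, n, m, dimnames = list(ids, NULL))
  ref_is_npb <- fix[, "REF"] == panel$npb_allele[idx]
  for (j in which(!is.na(idx))) {
    parts <- strsplit(ad[j, ], ",", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    if (isTRUE(ref_is_npb[j])) {
      npb[, idx[j]] <- a1; ind[, idx[j]] <- a2
    } else {
      npb[, idx[j]] <- a2; ind[, idx[j]] <- a1
    }
  }
  allele_depth_matrix(npb, ind, panel)
}

.read_allele_depths_tsv <- function(path, panel, individuals = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "chrom", "pos", "reads_npb", "reads_ind")
  if (!all(need %in% names(df)))
    stop("allele-depth TSV must have columns ", paste(need, collapse = ", "))
  if (is.null(individuals)) individuals <- unique(df$individual)
  idx <- match(paste(df$chrom, df$pos), paste(panel$chrom, panel$pos))
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " row(s) at SNPs not in panel; skipped")
    df <- df[!is.na(idx), ]; idx <- idx[!is.na(idx)]
  }
  n <- length(individuals); m <- nrow(panel)
  npb <- matrix(0L, n, m, dimnames = list(individuals, NULL))
  ind <- matrix(0L, n, m, dimnames = list(individuals, NULL))
  i <- match(df$individual, individuals)
  npb[cbind(i, idx)] <- as.integer(df$reads_npb)
  ind[cbind(i, idx)] <- as.integer(df$reads_ind)
  allele_depth_matrix(npb, ind, panel)
}

#' Write allele depths as TSV
#'
#' Long format with 0-based positions; only non-empty cells are written.
#' Round-trips through [read_allele_depths()].
#'
#' @param adm an [allele_depth_matrix()].
#' @param path output path.
#' @export
write_allele_depths <- function(adm, path) {
  nz <- which(adm$npb + adm$ind > 0, arr.ind = TRUE)
  df <- data.frame(individual = rownames(adm$npb)[nz[, 1]],
                   chrom = adm$panel$chrom[nz[, 2]],
                   pos = adm$panel$pos[nz[, 2]],
                   reads_npb = adm$npb[nz],
                   reads_ind = adm$ind[nz])
  df <- df[order(df$individual, df$chrom, df$pos), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a SNP panel as a minimal VCF
#'
#' Emits the two parental samples as homozygous diagnostic genotypes with the
#' NPB allele as REF.  Round-trips through [read_snp_panel()].
#'
#' @param panel a [snp_panel()].
#' @param path output path.
#' @param npb_sample,ind_sample sample column names to write.
#' @export
write_snp_panel <- function(panel, path, npb_sample = "NPB", ind_sample = "9311") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", npb_sample, ind_sample, sep = "\t")), con)
  if (nrow(panel) > 0) {
    writeLines(paste(panel$chrom, panel$pos + 1L, ".", panel$npb_allele,
                     panel$ind_allele, ".", "PASS", ".", "GT",
                     "0/0", "1/1", sep = "\t"), con)
  }
  invisible(path)
}

#' Homoeolog dosage matrix
#'
#' Individuals x bins matrix of the NPB homoeolog copy number d in {0..4}
#' (93-11 copies are 4 - d); `NA` marks bins with no informative SNPs.
#'
#' @param d integer matrix (individuals x bins), values in 0..4 or NA;
#'   rownames are individual ids.
#' @param grid the [genome_grid()] the columns are aligned to.
#' @param samples optional data.frame of per-individual metadata with at least
#'   column `individual`; conventional extras are `line`, `generation`,
#'   `cross` (one of `"NN99"`, `"99NN"`).
#' @return object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(d, grid, samples = NULL) {
  vals <- d[!is.na(d)]
  if (length(vals) && (any(vals < 0) || any(vals > 4)))
    stop("dosage values must be in 0..4 or NA")
  if (ncol(d) != grid$n_bins_total)
    stop("dosage matrix has ", ncol(d), " columns but grid has ",
         grid$n_bins_total, " bins")
  ids <- rownames(d)
  if (is.null(ids) || anyDuplicated(ids))
    stop("individual ids (rownames) must be present and unique")
  if (is.null(samples)) samples <- data.frame(individual = ids,
                                              stringsAsFactors = FALSE)
  if (!identical(samples$individual, ids))
    samples <- samples[match(ids, samples$individual), , drop = FALSE]
  storage.mode(d) <- "integer"
  structure(list(d = d, grid = grid, bins = grid_bins(grid), samples = samples),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d bins (%.1f%% called)\n",
              nrow(x$d), ncol(x$d), 100 * mean(!is.na(x$d))))
  invisible(x)
}

#' Write / read a dosage matrix as TSV
#'
#' Long TSV with header `individual, chrom, bin_start, bin_end, dosage`
#' (0-based half-open); uncalled bins are omitted and read back as `NA`.
#'
#' @param dm a [dosage_matrix()].
#' @param path file path.
#' @export
write_dosage <- function(dm, path) {
  called <- which(!is.na(dm$d), arr.ind = TRUE)
  df <- data.frame(individual = rownames(dm$d)[called[, 1]],
                   chrom = dm$bins$chrom[called[, 2]],
                   bin_start = dm$bins$start[called[, 2]],
                   bin_end = dm$bins$end[called[, 2]],
                   dosage = dm$d[called])
  df <- df[order(match(df$individual, rownames(dm$d)), df$chrom, df$bin_start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @param grid the [genome_grid()] of the written matrix.
#' @param samples optional sample metadata (see [dosage_matrix()]).
#' @export
read_dosage <- function(path, grid, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "chrom", "bin_start", "bin_end", "dosage")
  if (!all(need %in% names(df)))
    stop("dosage TSV must have columns ", paste(need, collapse = ", "))
  bad <- which(!(df$dosage %in% 0:4))
  if (length(bad))
    stop("invalid dosage value at line ", bad[1] + 1L, ": ", df$dosage[bad[1]])
  ids <- unique(df$individual)
  d <- matrix(NA_integer_, length(ids), grid$n_bins_total,
              dimnames = list(ids, NULL))
  if (nrow(df) > 0) {
    j <- bin_index(grid, df$chrom, df$bin_start)
    d[cbind(match(df$individual, ids), j)] <- as.integer(df$dosage)
  }
  dosage_matrix(d, grid, samples)
}

#' HE event (breakpoint) table
#'
#' @param individual,chrom,boundary,left_state,right_state vectors describing
#'   one breakpoint per row; `boundary` is the 0-based bp coordinate of the
#'   shared edge between the two adjacent bins whose dosage states differ.
#' @param low_resolution logical; TRUE where the breakpoint was bridged
#'   across a run of uncalled bins (located at the gap midpoint).
#' @return object of class `he_events` (a data.frame).
#' @export
he_events <- function(individual = character(), chrom = character(),
                      boundary = numeric(), left_state = integer(),
                      right_state = integer(),
                      low_resolution = logical(length(boundary))) {
  if (length(boundary) && any(left_state == right_state))
    stop("left and right states must differ at a breakpoint")
  df <- data.frame(individual = individual, chrom = chrom, boundary = boundary,
                   left_state = left_state, right_state = right_state,
                   low_resolution = low_resolution, stringsAsFactors = FALSE)
  class(df) <- c("he_events", "data.frame")
  df
}

#' Write HE breakpoints as a BED-like TSV
#'
#' Each breakpoint is written as the 0-based half-open uncertainty interval
#' `[boundary - bin_width, boundary)` with the individual and flanking dosage
#' states; rows are sorted by chrom, start, individual.
#'
#' @param he an [he_events()] table.
#' @param path output path.
#' @param bin_width analysis bin width in bp.
#' @export
write_he_bed <- function(he, path, bin_width = 5000) {
  start <- he$boundary - bin_width
  if (length(start) && any(start < 0)) {
    warning("breakpoint interval clamped at 0")
    start <- pmax(start, 0)
  }
  df <- data.frame(chrom = he$chrom, start = start, end = he$boundary,
                   individual = he$individual,
                   left_state = he$left_state, right_state = he$right_state)
  df <- df[order(df$chrom, df$start, df$individual), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene annotation table
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `cytonuclear_flag` (one of `"none"`,
#'   `"CCEC"`, `"CEC"`), `functional_divergence` (logical) and
#'   `known_trait_link` (free text).
#' @param grid optional [genome_grid()] used to bounds-check intervals.
#' @return the validated data.frame with class `annotation_table`.
#' @export
annotation_table <- function(genes, grid = NULL) {
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(genes)))
    stop("annotation needs columns ", paste(need, collapse = ", "))
  if (!"cytonuclear_flag" %in% names(genes)) genes$cytonuclear_flag <- "none"
  if (!all(genes$cytonuclear_flag %in% c("none", "CCEC", "CEC")))
    stop("cytonuclear_flag must be one of none, CCEC, CEC")
  if (!is.null(grid)) {
    len <- grid$chromosomes$length[match(genes$chrom, grid$chromosomes$chrom)]
    if (anyNA(len) || any(genes$start < 0) || any(genes$end > len))
      stop("gene interval outside chromosome bounds")
  }
  class(genes) <- c("annotation_table", "data.frame")
  genes
}
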