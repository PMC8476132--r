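#' Write a haplotype sample as a phased VCF
#'
#' Serializes a `haplotype_sample` as VCF 4.2.  The derived allele is
#' always ALT, the ancestral allele is REF and is repeated in the `AA`
#' INFO tag, and genotypes are phased (`GT` like `0|1`), pairing
#' consecutive haplotype columns into diploid individuals.  Internal
#' 0-based continuous coordinates are snapped to unique, strictly
#' increasing 1-based integer positions.
#'
#' @param sample a `haplotype_sample`.
#' @param path output file.
#' @param chrom chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sample, path, chrom = "1") {
  stopifnot(inherits(sample, "haplotype_sample"))
  H <- sample$n_hap
  if (H %% 2 != 0) stop("need an even number of haplotypes to pair diploids")
  S <- nrow(sample$geno)
  n_ind <- H %/% 2
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hzscan",
    sprintf("##contig=<ID=%s,length=%d>", chrom,
            as.integer(ceiling(sample$L))),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("ind%d", seq_len(n_ind))), collapse = "\t")
  )
  if (S == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  pos <- as.integer(floor(sample$positions)) + 1L
  for (i in seq_along(pos)[-1])  # enforce strictly increasing integers
    if (pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1L
  g1 <- sample$geno[, seq(1L, H, by = 2L), drop = FALSE]
  g2 <- sample$geno[, seq(2L, H, by = 2L), drop = FALSE]
  gt <- matrix(paste0(g1, "|", g2), nrow = S)
  body <- paste(chrom, pos, ".", "A", "T", ".", ".", "AA=A", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a polarized haplotype sample
#'
#' Loads a phased diploid VCF and polarizes every site to derived-allele
#' coding using the ancestral allele.  Sites are dropped (with a message
#' giving the counts) when they are multiallelic, lack a usable ancestral
#' allele, have an ancestral allele matching neither REF nor ALT, or are
#' monomorphic in the sample.  Unphased genotypes are an error.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param ancestral either the name of the INFO tag holding the ancestral
#'   allele (default `"AA"`) or a data frame with columns `pos` (1-based)
#'   and `allele`.
#' @param L chromosome length in bp; taken from the `##contig` header
#'   line if omitted.
#' @return A `haplotype_sample` (positions 0-based).
#' @export
read_polarized_variants <- function(path, ancestral = "AA", L = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(L)) {
    ln <- grep("^##contig=", v@meta, value = TRUE)
    if (length(ln)) {
      m <- regmatches(ln[1], regexpr("length=[0-9]+", ln[1]))
      if (length(m)) L <- as.numeric(sub("length=", "", m))
    }
  }
  fix <- v@fix
  S0 <- nrow(fix)
  if (is.null(S0) || S0 == 0) {
    if (is.null(L)) L <- 1
    return(haplotype_sample(matrix(integer(0), 0, 0), numeric(0), L = L))
  }
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- is.na(alt) | grepl(",", alt) | nchar(ref) != 1 |
    nchar(alt) != 1
  aa <- if (is.data.frame(ancestral)) {
    toupper(as.character(ancestral$allele[match(pos, ancestral$pos)]))
  } else {
    toupper(vcfR::extract.info(v, ancestral))
  }
  aa[aa %in% c("", ".", "N")] <- NA
  no_aa <- is.na(aa)
  mismatch <- !no_aa & !multi & aa != toupper(ref) & aa != toupper(alt)
  keep <- !(multi | no_aa | mismatch)
  gt <- v@gt[keep, -1, drop = FALSE]
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes found; the scan needs phased haplotypes")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  if (any(a1 == "." | a2 == "."))
    stop("missing genotypes are not supported")
  geno <- matrix(0L, nrow = sum(keep), ncol = 2 * ncol(gt))
  geno[, seq(1, ncol(geno), by = 2)] <- as.integer(a1 == "1")
  geno[, seq(2, ncol(geno), by = 2)] <- as.integer(a2 == "1")
  # re-orient sites where the ancestral allele is ALT
  flip <- aa[keep] == toupper(alt[keep])
  geno[flip, ] <- 1L - geno[flip, ]
  dac <- rowSums(geno)
  mono <- dac == 0 | dac == ncol(geno)
  n_drop <- c(multiallelic = sum(multi), no_ancestral = sum(no_aa),
              ancestral_mismatch = sum(mismatch),
              monomorphic = sum(mono))
  if (any(n_drop > 0))
    message("dropped sites: ",
            paste(names(n_drop), n_drop, sep = "=", collapse = ", "))
  if (is.null(L)) L <- max(pos) + 1
  haplotype_sample(geno[!mono, , drop = FALSE],
                   positions = pos[keep][!mono] - 1, L = L)
}

#' Write per-window tail counts as TSV
#'
#' @param tail a `tail_counts` object.
#' @param path output file.
#' @param d optional half-width: adds the `kappa_d` column.
#' @return `path`, invisibly.
#' @export
write_kappa_table <- function(tail, path, d = NULL) {
  stopifnot(inherits(tail, "tail_counts"))
  df <- data.frame(window = seq_len(tail$W),
                   start = (seq_len(tail$W) - 1) * tail$window_size,
                   end = seq_len(tail$W) * tail$window_size,
                   kappa = tail$kappa)
  if (!is.null(d)) df$kappa_d <- smoothed_counts(tail, d)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write outlier calls as BED
#'
#' Detection regions `[i-d, i+d]` in 0-based half-open BED coordinates,
#' one row per call (overlapping regions are not merged).
#'
#' @param calls a data frame from [call_outliers()].
#' @param path output file.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_outlier_bed <- function(calls, path, chrom = "1") {
  bed <- data.frame(chrom = rep(chrom, nrow(calls)),
                    start = as.integer(calls$start_bp),
                    end = as.integer(calls$end_bp),
                    name = sprintf("window_%d", calls$window),
                    score = calls$kappa)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Generate an on-disk fixture dataset
#'
#' Runs a scenario end to end and writes, under `dir`: a phased VCF of
#' the hybrid sample (`<prefix>.vcf`) and a truth/manifest JSON
#' (`<prefix>.json`) holding the scenario name, full parameter set, seed,
#' sampling generation and the 1-based truth window indices of the
#' incompatibility loci (absent for scenarios without epistatic
#' selection).  Given the same preset and seed the output is
#' byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param params a [sim_params()] object, e.g. from
#'   [scenario_params()]`(..., scale = "toy")`.
#' @param seed integer seed.
#' @param generation hybrid sampling generation; defaults to the last
#'   scheduled one.
#' @param window_size window width used for the truth window indices.
#' @param prefix file name prefix.
#' @return Named character vector with the paths written, invisibly.
#' @export
generate_fixture <- function(dir, params, seed,
                             generation = NULL, window_size = NULL,
                             prefix = "fixture") {
  validate_sim_params(params)
  if (is.null(generation))
    generation <- max(params$sample_generations)
  if (is.null(window_size))
    window_size <- attr(params, "window_size") %||% params$L / 1000
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_scenario(params, seed = seed,
                      sample_generations = generation)
  smp <- res$samples[[as.character(generation)]]
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  json_path <- file.path(dir, paste0(prefix, ".json"))
  write_vcf(smp, vcf_path)
  selected <- params$eps < 0 || params$s_a < 0 || params$s_b < 0
  truth <- list(
    scenario = attr(params, "scenario") %||% "custom",
    seed = seed, generation = generation,
    window_size = window_size,
    locus_positions = c(params$pos_A, params$pos_B),
    truth_windows = if (params$eps < 0)
      locus_windows(params, window_size) else integer(0),
    under_selection = selected,
    params = unclass(params)
  )
  jsonlite::write_json(truth, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(vcf = vcf_path, truth = json_path))
}
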