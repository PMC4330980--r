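#' Write a dose-response dataset to tab-delimited text
#'
#' Writes three files under a common stem: `<stem>.geno.tsv` (genotypes,
#' header = marker ids), `<stem>.resp.tsv` (responses, header =
#' concentrations) and, when truth metadata is present,
#' `<stem>.truth.txt` (key=value lines). The format is plain text so that
#' datasets are trivially inspectable.
#'
#' @param dataset a [DoseResponseExperiment-class].
#' @param stem path stem (directories must exist).
#' @return the stem, invisibly.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(dataset, stem) {
  stopifnot(is(dataset, "DoseResponseExperiment"))
  utils::write.table(dataset@genotypes, paste0(stem, ".geno.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Y <- dataset@responses
  colnames(Y) <- format(dataset@doses, trim = TRUE, digits = 15)
  utils::write.table(Y, paste0(stem, ".resp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- dataset@truth
  if (!is.null(tr)) {
    lines <- c(
      paste0("model_kind=", tr@modelKind),
      paste0("theta=", format(tr@theta, digits = 15)),
      paste0("causal_maf=", format(tr@causalMaf, digits = 15)),
      paste0("noise_scale=", format(tr@noiseScale, digits = 15)),
      paste0("noise_is_sd=", if (tr@noiseIsSd) "1" else "0"),
      paste0("causal_indices=", paste(tr@causalIndices, collapse = ",")),
      if (!is.null(dataset@meanCurve))
        paste0("mean_curve=",
               paste(format(dataset@meanCurve, digits = 15),
                     collapse = ",")))
    writeLines(lines, paste0(stem, ".truth.txt"))
  }
  invisible(stem)
}

readTruthFile <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stopInvalid("malformed truth file ", path, ": line ", bad[1],
                " is not key=value")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  spec <- geneticModelSpec(
    modelKind = vals[["model_kind"]],
    theta = as.numeric(vals[["theta"]]),
    causalMaf = as.numeric(vals[["causal_maf"]]),
    noiseScale = as.numeric(vals[["noise_scale"]]),
    noiseIsSd = vals[["noise_is_sd"]] == "1",
    causalIndices = as.integer(strsplit(vals[["causal_indices"]],
                                        ",")[[1]]))
  mc <- if ("mean_curve" %in% names(vals))
    as.numeric(strsplit(vals[["mean_curve"]], ",")[[1]]) else NULL
  list(spec = spec, meanCurve = mc)
}

#' Read a dose-response dataset written by [writeDataset()]
#'
#' Validates the genotype domain (entries must be 0, 1 or 2) and that
#' responses are numeric and finite; violations raise a parse error naming
#' the offending line (header = line 1).
#'
#' @param stem path stem used when writing.
#' @return a [DoseResponseExperiment-class]; truth metadata is restored
#'   when `<stem>.truth.txt` exists.
#' @export
readDataset <- function(stem) {
  gfile <- paste0(stem, ".geno.tsv")
  rfile <- paste0(stem, ".resp.tsv")
  if (!file.exists(gfile) || !file.exists(rfile))
    stopInvalid("dataset files not found at stem ", stem)
  G <- utils::read.delim(gfile, check.names = FALSE)
  Gm <- as.matrix(G)
  if (!is.numeric(Gm) || anyNA(Gm) || !all(Gm %in% c(0, 1, 2))) {
    badRow <- which(apply(is.na(suppressWarnings(
      matrix(as.numeric(Gm), nrow(Gm)))) |
      !matrix(as.numeric(Gm), nrow(Gm)) %in% c(0, 1, 2), 1, any))[1]
    stopInvalid("parse error in ", gfile, " near line ",
                badRow + 1L, ": genotype entries must be 0, 1 or 2")
  }
  storage.mode(Gm) <- "integer"
  Rraw <- utils::read.delim(rfile, check.names = FALSE,
                            colClasses = "character")
  Rm <- suppressWarnings(
    matrix(as.numeric(as.matrix(Rraw)), nrow(Rraw),
           dimnames = dimnames(as.matrix(Rraw))))
  if (anyNA(Rm)) {
    badRow <- which(apply(is.na(Rm), 1, any))[1]
    stopInvalid("parse error in ", rfile, " near line ", badRow + 1L,
                ": non-numeric response value")
  }
  dosesNum <- suppressWarnings(as.numeric(colnames(Rm)))
  if (anyNA(dosesNum))
    stopInvalid("parse error in ", rfile,
                " line 1: header must hold numeric concentrations")
  tfile <- paste0(stem, ".truth.txt")
  truth <- NULL; mc <- NULL
  if (file.exists(tfile)) {
    tt <- readTruthFile(tfile)
    truth <- tt$spec
    mc <- tt$meanCurve
  }
  new("DoseResponseExperiment", genotypes = Gm, responses = Rm,
      doses = dosesNum, meanCurve = mc, truth = truth)
}

#' Import a genotype matrix from a VCF file
#'
#' Converts the GT field of biallelic sites to minor-allele counts, with
#' the minor allele determined per site from the sample allele frequency
#' (ALT is flipped to REF counting when ALT is the major allele).
#' Multi-allelic sites are rejected and missing genotypes are an error —
#' no imputation is attempted.
#'
#' @param path VCF file (plain or bgzipped; requires the `vcfR` package).
#' @return integer matrix, individuals x sites, entries in {0, 1, 2};
#'   columns named by site ID (or `chrom_pos` when ID is missing).
#' @export
readGenotypesVCF <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopInvalid("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single-variant files drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE)))
    stopInvalid("multi-allelic sites are not supported; found at ",
                paste(fix[grepl(",", alt), "POS"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt) || any(gt %in% c(".", "./.", ".|.")))
    stopInvalid("missing genotypes are not supported (no imputation)")
  altCount <- function(x) {
    alleles <- strsplit(x, "[/|]")
    cnt <- vapply(alleles, function(a) {
      ai <- suppressWarnings(as.integer(a))
      if (anyNA(ai) || length(ai) != 2L || any(ai > 1L))
        return(NA_integer_)
      sum(ai)
    }, integer(1))
    cnt
  }
  cnt <- apply(gt, 2, altCount)              # sites x individuals -> sites rows
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = nrow(gt))
  if (anyNA(cnt))
    stopInvalid("unparseable or non-diploid GT entries found")
  # cnt: sites x individuals; flip sites where ALT is the major allele
  af <- rowMeans(cnt) / 2
  flip <- af > 0.5
  cnt[flip, ] <- 2L - cnt[flip, ]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  out <- t(cnt)
  colnames(out) <- ids
  storage.mode(out) <- "integer"
  out
}
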