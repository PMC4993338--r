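#' Risk-allele map for the 7-SNP telomere-length genetic risk score
#'
#' The seven variants associated with shorter leukocyte telomere length:
#' rs2736100 and rs2281929 (directly genotyped) and rs11125529, rs10936599,
#' rs7675998, rs9420907, rs8105767 (imputed). The risk/other alleles and the
#' chromosome/position fields shipped here are synthetic placeholders: the
#' effect-allele identities are not part of this package's inputs and must
#' be taken from the source GWAS for real use. The map is a plain data
#' frame and can equally be loaded from an edited YAML file with
#' [read_risk_allele_map()].
#'
#' @return Data frame with columns `rsid`, `risk_allele`, `other_allele`,
#'   `source`, `chrom`, `pos` (7 rows).
#' @export
default_risk_allele_map <- function() {
  data.frame(
    rsid = c("rs2736100", "rs2281929", "rs11125529", "rs10936599",
             "rs7675998", "rs9420907", "rs8105767"),
    risk_allele = c("A", "A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "G", "G", "G"),
    source = c("genotyped", "genotyped", "imputed", "imputed", "imputed",
               "imputed", "imputed"),
    chrom = as.character(1:7),
    pos = seq(1000L, 7000L, by = 1000L),
    stringsAsFactors = FALSE
  )
}

validate_risk_allele_map <- function(map) {
  need <- c("rsid", "risk_allele", "other_allele")
  if (!all(need %in% names(map))) {
    stop("risk-allele map needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(map) != 7 || anyDuplicated(map$rsid)) {
    stop("risk-allele map must have exactly 7 unique rsIDs")
  }
  invisible(map)
}

#' Read / write a risk-allele map as YAML
#'
#' @param path YAML file with a `snps` list of entries carrying `rsid`,
#'   `risk_allele`, `other_allele` and optional `source`, `chrom`, `pos`.
#' @return `read_risk_allele_map()` returns the map data frame;
#'   `write_risk_allele_map()` invisibly returns `path`.
#' @export
read_risk_allele_map <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$snps)) y$snps else y
  map <- do.call(rbind, lapply(entries, function(e) {
    data.frame(rsid = e$rsid, risk_allele = e$risk_allele,
               other_allele = e$other_allele,
               source = if (is.null(e$source)) NA_character_ else e$source,
               chrom = if (is.null(e$chrom)) NA_character_ else as.character(e$chrom),
               pos = if (is.null(e$pos)) NA_integer_ else as.integer(e$pos),
               stringsAsFactors = FALSE)
  }))
  validate_risk_allele_map(map)
  map
}

#' @rdname read_risk_allele_map
#' @param map Risk-allele map data frame.
#' @export
write_risk_allele_map <- function(map, path) {
  validate_risk_allele_map(map)
  yaml::write_yaml(list(snps = lapply(seq_len(nrow(map)), function(i) {
    as.list(map[i, , drop = FALSE])
  })), path)
  invisible(path)
}

#' Compute the un-weighted genetic risk score
#'
#' Sums the risk-allele dosages of the 7 LTL SNPs per individual; range 0
#' to 14, integer for hard calls. By default an individual with any missing
#' dosage gets a missing score (complete-case, matching the analysed
#' subset with full genetic information); `na_action = "mean_impute"`
#' replaces missing dosages by the per-SNP mean dosage instead.
#'
#' @param genotypes Data frame with `individual_id` and one dosage column
#'   (in `[0, 2]`) per SNP of `map`.
#' @param map Risk-allele map (see [default_risk_allele_map()]).
#' @param na_action `"omit"` (default) or `"mean_impute"`.
#' @return Named numeric vector of scores, names = individual IDs.
#' @export
compute_grs <- function(genotypes, map = default_risk_allele_map(),
                        na_action = c("omit", "mean_impute")) {
  na_action <- match.arg(na_action)
  validate_risk_allele_map(map)
  missing_snps <- setdiff(map$rsid, names(genotypes))
  if (length(missing_snps)) {
    stop("genotype table lacks SNP column(s): ",
         paste(missing_snps, collapse = ", "))
  }
  extra <- setdiff(setdiff(names(genotypes), "individual_id"), map$rsid)
  if (length(extra)) {
    stop("genotype column(s) not in the risk-allele map: ",
         paste(extra, collapse = ", "))
  }
  dos <- as.matrix(genotypes[, map$rsid, drop = FALSE])
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  if (na_action == "mean_impute" && anyNA(dos)) {
    for (j in seq_len(ncol(dos))) {
      nas <- is.na(dos[, j])
      if (any(nas)) dos[nas, j] <- mean(dos[, j], na.rm = TRUE)
    }
  }
  scores <- rowSums(dos)  # NA propagates under "omit"
  names(scores) <- genotypes$individual_id
  scores
}

#' Center genetic risk scores on their mean
#'
#' @param scores Numeric scores, possibly with missing entries.
#' @return Scores minus the mean of the non-missing entries (mean of the
#'   result is exactly 0 over non-missing entries). Idempotent.
#' @export
center_grs <- function(scores) {
  if (all(is.na(scores))) stop("all scores are missing")
  scores - mean(scores, na.rm = TRUE)
}

#' Read risk-allele dosages from a VCF file
#'
#' Extracts, for each individual, the dosage of the map's risk allele at
#' each of the 7 SNPs from a VCF v4.2 file. Hard genotype calls are read
#' from GT (`field = "GT"`); imputed dosages from DS (`field = "DS"`, taken
#' as the ALT dosage). The risk allele may be either REF or ALT;
#' multi-allelic sites and sites where neither REF nor ALT matches the
#' mapped risk allele are rejected.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param map Risk-allele map.
#' @param field `"GT"` or `"DS"`.
#' @return Genotype data frame (`individual_id` + one column per rsID).
#' @export
read_genotypes_vcf <- function(path, map = default_risk_allele_map(),
                               field = c("GT", "DS")) {
  field <- match.arg(field)
  validate_risk_allele_map(map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  absent <- setdiff(map$rsid, fix$ID)
  if (length(absent)) {
    stop("VCF lacks SNP(s): ", paste(absent, collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = field)
  samples <- colnames(gt)
  out <- data.frame(individual_id = samples, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(map))) {
    rs <- map$rsid[i]
    row <- match(rs, fix$ID)
    if (grepl(",", fix$ALT[row], fixed = TRUE)) {
      stop("multi-allelic site not supported: ", rs)
    }
    risk <- map$risk_allele[i]
    if (identical(fix$ALT[row], risk)) {
      risk_is_alt <- TRUE
    } else if (identical(fix$REF[row], risk)) {
      risk_is_alt <- FALSE
    } else {
      stop("risk allele ", risk, " for ", rs,
           " matches neither REF (", fix$REF[row], ") nor ALT (",
           fix$ALT[row], ")")
    }
    vals <- gt[row, ]
    if (field == "GT") {
      alt_dose <- vapply(strsplit(vals, "[/|]"), function(a) {
        if (anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a == "1")
      }, numeric(1))
    } else {
      alt_dose <- suppressWarnings(as.numeric(vals))
    }
    out[[rs]] <- if (risk_is_alt) alt_dose else 2 - alt_dose
  }
  out
}

#' Write a genotype table as a minimal VCF v4.2 file
#'
#' Hard-call dosages only: the risk allele is written as ALT and the other
#' allele as REF, so the GT field carries the risk-allele count directly
#' (0/0, 0/1, 1/1; missing as ./.). Positions come from the map (synthetic
#' placeholders in [default_risk_allele_map()]).
#'
#' @param genotypes Genotype data frame with integer dosages.
#' @param path Output path.
#' @param map Risk-allele map with `chrom` and `pos` columns.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(genotypes, path,
                                map = default_risk_allele_map()) {
  validate_risk_allele_map(map)
  samples <- genotypes$individual_id
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=twingrowth",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_string <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  body <- vapply(seq_len(nrow(map)), function(i) {
    d <- genotypes[[map$rsid[i]]]
    if (is.null(d)) stop("genotype table lacks ", map$rsid[i])
    if (any(!is.na(d) & d != round(d))) {
      stop("write_genotypes_vcf requires hard-call dosages (0/1/2)")
    }
    paste(c(map$chrom[i], map$pos[i], map$rsid[i], map$other_allele[i],
            map$risk_allele[i], ".", "PASS", ".", "GT", gt_string(d)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
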