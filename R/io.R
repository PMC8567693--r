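#' Read a phased trio VCF plus pedigree sidecar
#'
#' Parses a VCF of phased biallelic SNPs (GT fields `a|b`) and a tab-delimited
#' pedigree sidecar with columns `child`, `mother`, `father` (father `NA` for
#' mother--child duos). Multi-allelic and non-SNP records are rejected, as are
#' unphased (`/`-separated) genotypes. Missing alleles (`.`) are read as `NA`
#' and left for call-rate QC.
#'
#' @param path VCF file (plain text or bgzip).
#' @param ped_path tab-delimited pedigree sidecar.
#' @return a [trio_cohort].
#' @export
read_phased_vcf <- function(path, ped_path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic records are not supported")
  if (!all(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
           fix$REF %in% c("A", "C", "G", "T") &
           fix$ALT %in% c("A", "C", "G", "T")))
    stop("non-SNP record found (indel or symbolic allele)")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("phasing error: unphased ('/'-separated) genotype found")
  if (!all(gt %in% c("0|0", "0|1", "1|0", "1|1",
                     ".|.", ".|0", ".|1", "0|.", "1|.")))
    stop("unexpected GT value in VCF")
  allele <- function(k) {
    a <- substr(gt, k, k)
    a[a == "."] <- NA
    matrix(as.integer(a), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  h1 <- t(allele(1L)); h2 <- t(allele(3L))
  dr2 <- suppressWarnings(
    as.numeric(sub(".*DR2=([0-9.eE+-]+).*", "\\1", fix$INFO)))
  variants <- data.frame(
    id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  if (any(!is.na(dr2))) variants$dr2 <- dr2
  ped <- utils::read.delim(ped_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("child", "mother", "father") %in% names(ped)))
    stop("pedigree sidecar must have columns child, mother, father")
  ped$father[ped$father %in% c("NA", "")] <- NA
  sample_ids <- rownames(h1)
  role <- rep("father", length(sample_ids))
  role[sample_ids %in% ped$mother] <- "mother"
  role[sample_ids %in% ped$child] <- "child"
  in_ped <- sample_ids %in% c(ped$child, ped$mother, ped$father[!is.na(ped$father)])
  if (!all(in_ped))
    stop("pedigree error: samples in VCF absent from pedigree: ",
         paste(sample_ids[!in_ped], collapse = ", "))
  samples <- data.frame(sample_id = sample_ids, role = role,
                        stringsAsFactors = FALSE)
  trio_cohort(variants, samples, ped, h1, h2)
}

#' Write a phased trio cohort as VCF + pedigree sidecar
#'
#' Emits plain-text VCF v4.2 with phased GT and, when present, a per-variant
#' `DR2` INFO field, plus the pedigree sidecar accepted by
#' [read_phased_vcf()].
#'
#' @param cohort a [trio_cohort].
#' @param path output VCF path.
#' @param ped_path output pedigree path.
#' @return invisibly, `path`.
#' @export
write_phased_vcf <- function(cohort, path, ped_path) {
  v <- cohort$variants
  ids <- cohort$samples$sample_id
  info <- if ("dr2" %in% names(v)) sprintf("DR2=%g", v$dr2) else rep(".", nrow(v))
  a1 <- t(cohort$hap1); a2 <- t(cohort$hap2)   # variants x samples
  chr <- function(m) { m[is.na(m)] <- "."; m }
  gt <- matrix(paste(chr(a1), chr(a2), sep = "|"),
               nrow = nrow(v), dimnames = list(NULL, ids))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DR2,Number=1,Type=Float,Description=\"Imputation dosage R-squared\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  ped <- cohort$pedigree
  ped$father[is.na(ped$father)] <- "NA"
  utils::write.table(ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

valid_traits <- c("SBP", "DBP", "MAP", "PP", "BMI", "T2D", "HbA1c")

#' Read GWAS summary statistics
#'
#' Tab-delimited with header columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `beta` (normalized effect size per
#' effect-allele copy, trait SD units), `p_value`, `trait`.
#'
#' @param path file path.
#' @param trait trait to select; one of SBP, DBP, MAP, PP, BMI, T2D, HbA1c.
#' @return data.frame of records for the requested trait.
#' @export
read_summary_stats <- function(path, trait) {
  if (!trait %in% valid_traits)
    stop("unknown trait label: ", trait)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "p_value", "trait")
  if (!all(need %in% names(d)))
    stop("summary statistics must have columns: ", paste(need, collapse = ", "))
  if (!all(d$trait %in% valid_traits))
    stop("unknown trait label in table: ",
         paste(unique(setdiff(d$trait, valid_traits)), collapse = ", "))
  d$effect_allele <- toupper(d$effect_allele)
  d$other_allele <- toupper(d$other_allele)
  if (any(d$p_value <= 0 | d$p_value > 1))
    stop("p_value outside (0, 1]")
  if (any(d$effect_allele == d$other_allele))
    stop("effect_allele equals other_allele for some variant")
  d[d$trait == trait, , drop = FALSE]
}

#' @rdname read_summary_stats
#' @param sumstats data.frame in the layout produced by [read_summary_stats()]
#'   (any mix of traits).
#' @export
write_summary_stats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a perinatal reference chart
#'
#' Chart rows are keyed by (integer gestational week, fetal sex, parity) and
#' give mean/SD of birth weight and placental weight in grams for the stratum.
#'
#' @param path tab-delimited file with columns `week`, `sex`, `parity`,
#'   `bw_mean`, `bw_sd`, `pw_mean`, `pw_sd`.
#' @return data.frame of class `reference_chart`.
#' @export
read_reference_chart <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("week", "sex", "parity", "bw_mean", "bw_sd", "pw_mean", "pw_sd")
  if (!all(need %in% names(d)))
    stop("reference chart must have columns: ", paste(need, collapse = ", "))
  if (any(d$bw_sd <= 0) || any(d$pw_sd <= 0))
    stop("reference chart SD must be > 0")
  if (anyDuplicated(d[c("week", "sex", "parity")]))
    stop("duplicate chart stratum")
  class(d) <- c("reference_chart", "data.frame")
  d
}

#' @rdname read_reference_chart
#' @param chart a `reference_chart` data.frame.
#' @export
write_reference_chart <- function(chart, path) {
  utils::write.table(as.data.frame(chart), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write the variant vasculature-annotation table
#'
#' Columns: `variant_id`, `vasc_class` (one of `vasculature-related`,
#' `unlikely related`, `unknown`), `sbp_increasing_allele`,
#' `trait_memberships` (comma-joined subset of SBP,DBP,MAP,PP) and
#' `dbp_discordant` (logical: the SBP-increasing allele decreases DBP).
#'
#' @param path tab-delimited file.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "vasc_class", "sbp_increasing_allele",
            "trait_memberships", "dbp_discordant")
  if (!all(need %in% names(d)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  classes <- c("vasculature-related", "unlikely related", "unknown")
  if (!all(d$vasc_class %in% classes))
    stop("vasc_class must be one of: ", paste(classes, collapse = ", "))
  if (!all(d$sbp_increasing_allele %in% c("A", "C", "G", "T")))
    stop("sbp_increasing_allele must be a nucleotide")
  d$dbp_discordant <- as.logical(d$dbp_discordant)
  d
}

#' @rdname read_annotation
#' @param annotation annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write the phenotype tables
#'
#' Phenotypes live in two tab-delimited files: a pair-level table (one row per
#' mother--child pair) and a long blood-pressure table with one row per
#' antenatal BP reading.
#'
#' @param path pair-level table: `pair_id`, `pre_pregnancy_bmi` (kg/m2),
#'   `birth_weight` (g), `placental_weight` (g),
#'   `gestational_age_at_delivery` (decimal weeks), `fetal_sex`, `parity`
#'   (`nulliparous`/`parous`), `hypertension_flag` (`none`/`chronic`/`HDP`).
#' @param bp_path long BP table: `pair_id`, `gestational_week`, `sbp`, `dbp`
#'   (mmHg).
#' @return list of class `pheno_table` with elements `pairs` and `bp`.
#' @export
read_phenotypes <- function(path, bp_path) {
  pairs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "pre_pregnancy_bmi", "birth_weight", "placental_weight",
            "gestational_age_at_delivery", "fetal_sex", "parity",
            "hypertension_flag")
  if (!all(need %in% names(pairs)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (any(pairs$pre_pregnancy_bmi <= 0)) stop("BMI must be positive")
  if (!all(pairs$parity %in% c("nulliparous", "parous")))
    stop("parity must be nulliparous/parous")
  if (!all(pairs$hypertension_flag %in% c("none", "chronic", "HDP")))
    stop("hypertension_flag must be none/chronic/HDP")
  bp <- utils::read.delim(bp_path, stringsAsFactors = FALSE)
  if (!all(c("pair_id", "gestational_week", "sbp", "dbp") %in% names(bp)))
    stop("BP table must have pair_id, gestational_week, sbp, dbp")
  if (any(bp$dbp >= bp$sbp) || any(bp$dbp <= 0))
    stop("each BP observation requires sbp > dbp > 0")
  structure(list(pairs = pairs, bp = bp), class = "pheno_table")
}

#' @rdname read_phenotypes
#' @param phenotypes a `pheno_table`.
#' @export
write_phenotypes <- function(phenotypes, path, bp_path) {
  utils::write.table(phenotypes$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(phenotypes$bp, bp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write serial ultrasound EFW observations
#'
#' Long tab-delimited table: `pair_id`, `gestational_week` (decimal weeks,
#' strictly increasing within a fetus), `efw` (estimated fetal weight, g).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ultrasound <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pair_id", "gestational_week", "efw") %in% names(d)))
    stop("ultrasound table must have pair_id, gestational_week, efw")
  if (any(d$efw <= 0)) stop("efw must be positive")
  bad <- unlist(lapply(split(d$gestational_week, d$pair_id),
                       function(w) any(diff(w) <= 0)))
  if (any(bad))
    stop("gestational weeks must be strictly increasing within a fetus: ",
         paste(names(bad)[bad], collapse = ", "))
  d
}

#' @rdname read_ultrasound
#' @param ultrasound ultrasound data.frame.
#' @export
write_ultrasound <- function(ultrasound, path) {
  utils::write.table(ultrasound, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
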