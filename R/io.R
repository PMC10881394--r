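# Readers and writers: TSV bundle round-trip with provenance comment
# headers, minimal VCF genotype export/import, YAML pipeline
# configuration.

provenance_header <- function(stage, seed = NULL, extra = character()) {
  c(
    sprintf("# cytovar %s", as.character(utils::packageVersion("cytovar"))),
    sprintf("# stage: %s", stage),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    extra
  )
}

#' Write a table as TSV with a provenance header
#'
#' UTF-8, tab-separated, header row, `"."` for missing values, preceded
#' by `#` comment lines carrying provenance (package version, stage,
#' seed, content hash) that downstream tools can skip.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param stage Stage label recorded in the header.
#' @param seed Optional seed recorded in the header.
#' @export
write_tsv_prov <- function(x, path, stage = "table", seed = NULL) {
  hdr <- provenance_header(stage, seed,
                           sprintf("# content_hash: %s", rlang::hash(x)))
  writeLines(hdr, path)
  readr::write_tsv(x, path, na = ".", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path File path; `#` lines are skipped, `"."` read as NA.
#' @param ... Passed to [readr::read_tsv()].
#' @export
read_tsv_prov <- function(path, ...) {
  readr::read_tsv(path, comment = "#", na = ".", show_col_types = FALSE,
                  progress = FALSE, ...)
}

.bundle_tables <- c("covariates", "cytokines", "lloq", "cells", "proteins",
                    "methylation", "cpg_positions", "genotypes", "snp_map",
                    "tss")

#' Write a cohort bundle to a directory
#'
#' One TSV per table (see [read_bundle()] for the inverse), the
#' ground-truth ledger as `truth_*.tsv` files, and optionally the
#' genotypes as a minimal VCF v4.2.
#'
#' @param bundle A `"cohort_bundle"`.
#' @param dir Output directory (created if needed).
#' @param vcf Also write `genotypes.vcf`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in .bundle_tables) {
    if (!is.null(bundle[[tb]])) {
      write_tsv_prov(bundle[[tb]], file.path(dir, paste0(tb, ".tsv")),
                     stage = paste0("bundle/", tb), seed = bundle$seed)
    }
  }
  tr <- bundle$truth
  if (!is.null(tr)) {
    for (nm in names(tr)) {
      if (is.data.frame(tr[[nm]])) {
        write_tsv_prov(tr[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                       stage = paste0("truth/", nm), seed = bundle$seed)
      }
    }
  }
  meta <- tibble(
    key = c("seed", "null_condition", "responder_stimulation"),
    value = as.character(c(bundle$seed, bundle$null_condition,
                           bundle$responder_stimulation))
  )
  write_tsv_prov(meta, file.path(dir, "bundle_meta.tsv"), stage = "meta")
  if (vcf && !is.null(bundle$genotypes)) {
    write_genotype_vcf(bundle$genotypes, bundle$snp_map,
                       file.path(dir, "genotypes.vcf"))
  }
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' Reads the TSVs written by [write_bundle()], validates the schema
#' (unique donor ids; donors aligned across tables) and reports
#' mismatch counts. A duplicated donor id is a hard error naming the
#' id; a donor-id mismatch above `max_mismatch` of donors is a hard
#' error too.
#'
#' @param dir Directory written by [write_bundle()].
#' @param max_mismatch Tolerated fraction of donors missing from a
#'   table before erroring.
#' @return A `"cohort_bundle"` (without the rebuilt `truth` closure;
#'   truth tables are under `$truth`).
#' @export
read_bundle <- function(dir, max_mismatch = 0.05) {
  out <- list()
  for (tb in .bundle_tables) {
    f <- file.path(dir, paste0(tb, ".tsv"))
    if (file.exists(f)) out[[tb]] <- read_tsv_prov(f)
  }
  if (is.null(out$covariates)) {
    abort_data(sprintf("no covariates.tsv found in `%s`.", dir))
  }
  dup <- out$covariates$donor[duplicated(out$covariates$donor)]
  if (length(dup)) {
    abort_data(sprintf("duplicated donor id(s) in covariates: %s",
                       paste(unique(dup), collapse = ", ")))
  }
  donors <- out$covariates$donor
  for (tb in setdiff(names(out), c("lloq", "cpg_positions", "snp_map", "tss"))) {
    if (!"donor" %in% names(out[[tb]])) next
    missing_n <- length(setdiff(donors, out[[tb]]$donor))
    if (missing_n) {
      inform(sprintf("%s: %d donor(s) absent.", tb, missing_n))
      if (missing_n / length(donors) > max_mismatch) {
        abort_data(sprintf(
          "%s misses %d of %d donors (> %.0f%% allowed).",
          tb, missing_n, length(donors), 100 * max_mismatch
        ))
      }
    }
    dup <- unique(out[[tb]]$donor[duplicated(out[[tb]]$donor)])
    if (tb != "cytokines" && length(dup)) {
      abort_data(sprintf("duplicated donor id(s) in %s: %s", tb,
                         paste(dup, collapse = ", ")))
    }
  }
  meta_f <- file.path(dir, "bundle_meta.tsv")
  if (file.exists(meta_f)) {
    meta <- read_tsv_prov(meta_f)
    out$seed <- as.integer(meta$value[meta$key == "seed"])
    out$null_condition <- meta$value[meta$key == "null_condition"]
    out$responder_stimulation <- meta$value[meta$key == "responder_stimulation"]
  }
  truth_files <- list.files(dir, pattern = "^truth_.*\\.tsv$",
                            full.names = TRUE)
  if (length(truth_files)) {
    tr <- lapply(truth_files, read_tsv_prov)
    names(tr) <- sub("^truth_(.*)\\.tsv$", "\\1", basename(truth_files))
    out$truth <- structure(tr, class = "truth_ledger")
  }
  structure(out, class = "cohort_bundle")
}

#' Write genotypes as a minimal VCF v4.2
#'
#' GT field only; dosages 0/1/2 become `0/0`, `0/1`, `1/1`; missing
#' becomes `./.`. REF/ALT are placeholder alleles (`A`/`B` semantics
#' are not tracked by the dosage representation).
#'
#' @param genotypes Dosage tibble (donor + SNP columns).
#' @param snp_map Tibble (id, chrom, position).
#' @param path Output path.
#' @export
write_genotype_vcf <- function(genotypes, snp_map, path) {
  snps <- setdiff(names(genotypes), "donor")
  donors <- genotypes$donor
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=cytovar",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", donors), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (s in snps) {
    i <- match(s, snp_map$id)
    d <- genotypes[[s]]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(
      as.character(snp_map$chrom[i] %||% "1"),
      format(snp_map$position[i] %||% 1, scientific = FALSE, trim = TRUE),
      s, "A", "G", ".", "PASS", ".", "GT", gt
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Decodes the GT field to additive dosages (count of ALT alleles;
#' `./.` to NA). Uses vcfR when installed, otherwise a minimal parser
#' sufficient for the GT-only files written by
#' [write_genotype_vcf()].
#'
#' @param path VCF path.
#' @return List (genotypes, snp_map).
#' @export
read_genotype_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    map <- tibble(id = fix$ID, chrom = as.character(fix$CHROM),
                  position = as.numeric(fix$POS))
    donors <- colnames(gt)
    dos <- apply(gt, c(1, 2), decode_gt)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(body[1], "\t")[[1]]
    donors <- hdr[-(1:9)]
    recs <- strsplit(body[-1], "\t")
    map <- tibble(
      id = purrr::map_chr(recs, 3),
      chrom = purrr::map_chr(recs, 1),
      position = as.numeric(purrr::map_chr(recs, 2))
    )
    dos <- t(vapply(recs, function(r) {
      vapply(r[-(1:9)], decode_gt, numeric(1))
    }, numeric(length(donors))))
  }
  geno <- tibble(donor = donors)
  for (j in seq_len(nrow(map))) geno[[map$id[j]]] <- as.numeric(dos[j, ])
  list(genotypes = geno, snp_map = map)
}

decode_gt <- function(g) {
  if (is.na(g)) return(NA_real_)
  g <- strsplit(sub(":.*", "", g), "[/|]")[[1]]
  if (any(g == ".") || !length(g)) return(NA_real_)
  as.numeric(sum(g != "0"))
}

#' Load and validate a pipeline configuration from YAML
#'
#' The YAML mirrors the analysis defaults: input table paths, the
#' stimulation list with its null and responder-restricted
#' designations, the stimulation-to-main-cell-subset map, thresholds
#' (induction 0.30, screen alpha 0.01, CpG FDR 0.05, MAF 0.05, cis
#' window 1e6, cis/trans detection 1e-3/1e-5, Bonferroni alpha 0.05,
#' variance inclusion q 0.05) and seeds. Probability thresholds must
#' lie in (0, 1), the window must be positive, and referenced files
#' must exist.
#'
#' @param path YAML file path.
#' @return List of class `"pipeline_config"`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("config file `%s` not found.", path), "path")
  }
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    thresholds = list(
      induction = 0.30, screen_alpha = 0.01, cpg_fdr = 0.05,
      maf = 0.05, cis_window = 1e6, cis_detection = 1e-3,
      trans_detection = 1e-5, bonferroni_alpha = 0.05, variance_q = 0.05
    ),
    seeds = list(responders = 1L),
    null_condition = "null",
    log_level = "info"
  )
  cfg <- modifyList(defaults, cfg)
  th <- cfg$thresholds
  for (nm in c("induction", "screen_alpha", "cpg_fdr", "maf",
               "cis_detection", "trans_detection", "bonferroni_alpha",
               "variance_q")) {
    v <- th[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      abort_config(sprintf("threshold `%s` must lie in (0, 1).", nm), nm)
    }
  }
  if (!is.numeric(th$cis_window) || th$cis_window <= 0) {
    abort_config("`cis_window` must be positive.", "cis_window")
  }
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) {
      abort_config(sprintf("input file `%s` does not exist.", p), "paths")
    }
  }
  structure(cfg, class = "pipeline_config")
}
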