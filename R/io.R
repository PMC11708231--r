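#' Read a population map
#'
#' Two-column TSV (no header): sample identifier, leaf label (1-5). In
#' haploid mode exactly one sample per leaf is required; in frequency mode
#' any number, and per-site allele frequencies are computed over all of a
#' leaf's samples.
#'
#' @param path Popmap file.
#' @param mode `"haploid"` or `"frequency"`.
#' @return A `population_map`: list of sample-id vectors named "1".."5",
#'   with attribute `mode`.
#' @export
read_popmap <- function(path, mode = c("haploid", "frequency")) {
  mode <- match.arg(mode)
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("sample", "leaf"),
                    colClasses = c("character", "character"))
  popmap(split(tab$sample, tab$leaf), mode = mode)
}

#' @rdname read_popmap
#' @param samples Named list ("1".."5") of sample-id vectors.
#' @export
popmap <- function(samples, mode = c("haploid", "frequency")) {
  mode <- match.arg(mode)
  if (!setequal(names(samples), as.character(1:5))) {
    stop("popmap must map exactly the five leaf labels 1..5")
  }
  samples <- samples[as.character(1:5)]
  if (mode == "haploid" && any(lengths(samples) != 1L)) {
    stop("haploid mode requires exactly one designated sample per leaf")
  }
  structure(samples, mode = mode, class = "population_map")
}

#' Read site observations from a VCF or a plain site table
#'
#' VCF input (optionally gzipped, parsed with the vcfR package) is reduced
#' to biallelic SNP records; per leaf either the first allele of the
#' designated sample's genotype (haploid mode) or the alt-allele frequency
#' over all mapped samples' called alleles (frequency mode). Plain tables
#' are TSV with columns `chrom`, `pos`, then five taxon columns in leaf
#' order (header row names the taxa).
#'
#' @param path Input file.
#' @param popmap A [popmap()] (required for VCF input).
#' @param format `"auto"` (by extension), `"vcf"` or `"table"`.
#' @return Site data frame (`chrom`, `pos`, five taxon columns) with
#'   attribute `skipped` (named counts of skipped records). Unusable taxa
#'   entries are `NA` and counted when patterns are accumulated.
#' @export
read_sites <- function(path, popmap = NULL, format = c("auto", "vcf",
                                                       "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "table"
  }
  if (format == "table") {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(tab) != 7L) stop("site table needs chrom, pos + 5 taxon columns")
    names(tab)[1:2] <- c("chrom", "pos")
    return(tab)
  }
  if (is.null(popmap)) stop("VCF input requires a popmap")
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  mode <- attr(popmap, "mode")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  needed <- unlist(popmap)
  miss <- setdiff(needed, colnames(gt))
  if (length(miss)) {
    stop("samples missing from VCF header: ", paste(miss, collapse = ", "))
  }
  skipped <- c(multiallelic = 0L, non_snp = 0L)
  keep <- rep(TRUE, nrow(fix))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt)
  skipped["multiallelic"] <- sum(multi)
  non_snp <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L | is.na(alt))
  skipped["non_snp"] <- sum(non_snp)
  keep <- !multi & !non_snp
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  ref <- ref[keep]
  alt <- alt[keep]
  n <- sum(keep)
  out <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  for (leaf in as.character(1:5)) {
    cols <- gt[, popmap[[leaf]], drop = FALSE]
    if (mode == "haploid") {
      g <- cols[, 1L]
      first <- substr(g, 1L, 1L)
      val <- ifelse(is.na(g) | !first %in% c("0", "1"), NA_character_,
                    ifelse(first == "0", ref, alt))
    } else {
      val <- vapply(seq_len(n), function(i) {
        al <- unlist(strsplit(cols[i, ], "[/|]"))
        al <- al[al %in% c("0", "1")]
        if (length(al) == 0L) NA_real_ else mean(al == "1")
      }, 0)
    }
    out[[paste0("taxon", leaf)]] <- val
  }
  attr(out, "skipped") <- skipped
  out
}

#' Read a simulator configuration
#'
#' YAML file with keys `shape` (S/A/Q), optional `node_times` (map),
#' `sampling_times` (5 values), `lambda`, `mu`, `beta`, `n_patterns`,
#' `seed`, and `edges` (list of `"src>tgt"` labels or maps with `event`,
#' optional `beta`, `t_admix`, `t_join`).
#'
#' @param path YAML config file.
#' @return List with `model` (an `admixture_graph_model`), `n_patterns`,
#'   `seed`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$shape)) stop("config needs a tree shape")
  nt <- if (!is.null(cfg$node_times)) unlist(cfg$node_times) else NULL
  model <- species_model(cfg$shape, node_times = nt,
                         sampling_times = if (!is.null(cfg$sampling_times))
                           as.numeric(cfg$sampling_times) else rep(0, 5),
                         lambda = if (!is.null(cfg$lambda)) cfg$lambda else 1,
                         mu = if (!is.null(cfg$mu)) cfg$mu else 1e-4)
  beta0 <- if (!is.null(cfg$beta)) cfg$beta else 0.1
  for (e in cfg$edges) {
    if (is.character(e)) {
      model <- add_gene_flow(model, e, beta = beta0)
    } else {
      model <- add_gene_flow(model, e$event,
                             beta = if (!is.null(e$beta)) e$beta else beta0,
                             t_admix = e$t_admix, t_join = e$t_join)
    }
  }
  list(model = model,
       n_patterns = if (!is.null(cfg$n_patterns)) cfg$n_patterns else 1e5,
       seed = cfg$seed)
}
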