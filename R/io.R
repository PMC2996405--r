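GENO_META_COLS <- c("snp_id", "chrom_class", "position", "ancestral_allele")
CHROM_CLASSES <- c("autosome", "X", "Y", "other")
FUNC_CLASSES <- c("nonsynonymous", "synonymous", "other")

#' Individual identifiers of a genotype table
#'
#' A genotype table is a wide tibble with four metadata columns
#' (`snp_id`, `chrom_class`, `position`, `ancestral_allele`) followed by one
#' integer column per individual holding the ancestral-allele dosage
#' (0, 1, 2 or `NA` for a missing call).
#'
#' @param genotypes A genotype tibble.
#' @return Character vector of individual ids (the dosage column names).
#' @export
genotype_individuals <- function(genotypes) {
  setdiff(names(genotypes), GENO_META_COLS)
}

#' Extract the dosage matrix from a genotype table
#'
#' @param genotypes A genotype tibble (see [genotype_individuals()]).
#' @return Integer matrix, SNPs in rows (named by `snp_id`), individuals in
#'   columns.
#' @export
genotype_matrix <- function(genotypes) {
  inds <- genotype_individuals(genotypes)
  m <- as.matrix(genotypes[, inds, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genotypes$snp_id
  m
}

validate_genotypes <- function(genotypes, source = "genotypes") {
  missing_meta <- setdiff(GENO_META_COLS, names(genotypes))
  if (length(missing_meta) > 0) {
    abort(sprintf("%s: missing columns %s", source,
                  paste(missing_meta, collapse = ", ")))
  }
  if (anyDuplicated(genotypes$snp_id)) {
    abort(sprintf("%s: duplicated snp_id values", source))
  }
  bad_class <- setdiff(unique(genotypes$chrom_class), CHROM_CLASSES)
  if (length(bad_class) > 0) {
    abort(sprintf("%s: unknown chrom_class %s", source,
                  paste(bad_class, collapse = ", ")))
  }
  m <- genotype_matrix(genotypes)
  bad <- which(!is.na(m) & !(m %in% 0:2))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(m))
    abort(sprintf(
      "%s: dosage outside {0,1,2,NA} at SNP '%s', individual '%s'",
      source, rownames(m)[i[1]], colnames(m)[i[2]]))
  }
  invisible(genotypes)
}

#' Build a population table
#'
#' @param pop_id Character vector of population labels.
#' @param latitude Signed decimal latitude in degrees, one per population,
#'   in \[-90, 90\].
#' @param members List of character vectors; individual ids per population.
#'   Sets must be pairwise disjoint.
#' @return Tibble with columns `pop_id`, `latitude`, `members` (list-column)
#'   and `size`.
#' @export
population_table <- function(pop_id, latitude, members) {
  if (any(latitude < -90 | latitude > 90)) {
    bad <- pop_id[latitude < -90 | latitude > 90][1]
    abort(sprintf("latitude out of [-90, 90] for population '%s'", bad))
  }
  if (anyDuplicated(pop_id)) abort("duplicated pop_id")
  all_members <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- all_members[duplicated(all_members)][1]
    abort(sprintf("individual '%s' listed in more than one population", dup))
  }
  sizes <- lengths(members)
  if (any(sizes < 1)) abort("every population needs at least one member")
  tibble(pop_id = pop_id, latitude = as.numeric(latitude),
         members = unname(members), size = as.integer(sizes))
}

#' Build a SNP annotation table
#'
#' @param snp_id Character vector of SNP ids.
#' @param genes List of character vectors; gene symbols assigned to each SNP
#'   (possibly empty).
#' @param func_class One of `"nonsynonymous"`, `"synonymous"`, `"other"` per
#'   SNP.
#' @return Tibble with columns `snp_id`, `genes` (list-column), `func_class`.
#' @export
snp_annotation <- function(snp_id, genes, func_class) {
  bad <- setdiff(unique(func_class), FUNC_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown func_class %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(snp_id)) abort("duplicated snp_id in annotation")
  tibble(snp_id = snp_id, genes = unname(genes), func_class = func_class)
}

#' Read a genotype matrix
#'
#' Three dialects are supported. The native tab-separated layout has columns
#' `snp_id`, `chrom_class`, `position`, `ancestral_allele` and then one
#' column per individual with ancestral-allele dosages in \{0,1,2\} (`NA`
#' for missing). PLINK-style `.ped`/`.map` pairs and minimal VCF (GT field)
#' encode alleles as bases; these are reoriented to ancestral-allele counts
#' using `ancestral` (for ped/map) or the VCF `AA` INFO tag. Y-class SNPs
#' are loaded as-is; they are dropped later by [intragenic_filter()].
#'
#' @param path Path to the `.tsv`, `.ped` or `.vcf` file (for ped/map, the
#'   `.map` file must sit next to the `.ped`).
#' @param format One of `"auto"`, `"tsv"`, `"pedmap"`, `"vcf"`; `"auto"`
#'   picks by file extension.
#' @param ancestral Optional tibble `snp_id`, `ancestral_allele` giving the
#'   ancestral base per SNP; required for ped/map input.
#' @param annotation Optional annotation tibble; SNPs present in the
#'   genotypes but absent from it are reported with a warning and retained.
#' @return A genotype tibble (see [genotype_individuals()]).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "pedmap", "vcf"),
                           ancestral = NULL, annotation = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     ped = "pedmap", map = "pedmap", vcf = "vcf", "tsv")
  }
  g <- switch(format,
              tsv = read_genotypes_tsv(path),
              pedmap = read_genotypes_pedmap(path, ancestral),
              vcf = read_genotypes_vcf(path))
  validate_genotypes(g, source = path)
  if (!is.null(annotation)) {
    unknown <- setdiff(g$snp_id, annotation$snp_id)
    if (length(unknown) > 0) {
      warn(sprintf(
        "%d SNP(s) absent from the annotation (retained with empty gene set): %s",
        length(unknown), paste(head(unknown, 5), collapse = ", ")))
    }
  }
  g
}

read_genotypes_tsv <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("NA", ""))
  inds <- setdiff(names(g), GENO_META_COLS)
  for (j in inds) {
    v <- g[[j]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & !(v %in% c("0", "1", "2")))[1]
      abort(sprintf("%s: unknown allele code '%s' at line %d, column '%s'",
                    path, v[bad], bad + 1L, j))
    }
    g[[j]] <- as.integer(v)
  }
  g$position <- as.integer(g$position)
  g
}

read_genotypes_pedmap <- function(ped_path, ancestral) {
  if (is.null(ancestral)) {
    abort("ped/map input needs `ancestral` (tibble snp_id, ancestral_allele)")
  }
  prefix <- sub("\\.(ped|map)$", "", ped_path)
  map <- readr::read_tsv(paste0(prefix, ".map"),
                         col_names = c("chrom", "snp_id", "cm", "position"),
                         col_types = "ccdi", progress = FALSE)
  ped <- readr::read_delim(paste0(prefix, ".ped"), delim = " ",
                           col_names = FALSE, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp) {
    abort(sprintf("%s.ped: expected %d allele columns, found %d",
                  prefix, 2 * n_snp, ncol(ped) - 6))
  }
  iid <- ped[[2]]
  anc <- ancestral$ancestral_allele[match(map$snp_id, ancestral$snp_id)]
  if (anyNA(anc)) {
    abort(sprintf("no ancestral allele for SNP '%s'",
                  map$snp_id[which(is.na(anc))[1]]))
  }
  dos <- matrix(NA_integer_, n_snp, nrow(ped))
  allele_ok <- c("A", "C", "G", "T", "0")
  for (s in seq_len(n_snp)) {
    a1 <- toupper(ped[[6 + 2 * s - 1]])
    a2 <- toupper(ped[[6 + 2 * s]])
    bad <- which(!(a1 %in% allele_ok) | !(a2 %in% allele_ok))
    if (length(bad) > 0) {
      abort(sprintf("%s.ped: unknown allele code at line %d, SNP '%s'",
                    prefix, bad[1], map$snp_id[s]))
    }
    miss <- a1 == "0" | a2 == "0"
    d <- (a1 == anc[s]) + (a2 == anc[s])
    d[miss] <- NA_integer_
    dos[s, ] <- as.integer(d)
  }
  colnames(dos) <- iid
  bind_cols(
    tibble(snp_id = map$snp_id,
           chrom_class = chrom_to_class(map$chrom),
           position = map$position,
           ancestral_allele = anc),
    as_tibble(dos))
}

chrom_to_class <- function(chrom) {
  chrom <- toupper(as.character(chrom))
  dplyr::case_when(
    chrom %in% c(as.character(1:22), paste0("CHR", 1:22), "AUTOSOME") ~ "autosome",
    chrom %in% c("X", "23", "CHRX") ~ "X",
    chrom %in% c("Y", "24", "CHRY") ~ "Y",
    TRUE ~ "other")
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  aa <- vcfR::extract.info(v, "AA")
  if (all(is.na(aa))) abort(sprintf("%s: no AA (ancestral allele) INFO tag", path))
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  known <- c("0/0", "0|0", "0/1", "0|1", "1/0", "1|0", "1/1", "1|1",
             "./.", ".|.", ".")
  bad <- which(!is.na(gt) & !(gt %in% known))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(gt))
    abort(sprintf("%s: unknown GT '%s' for SNP '%s'", path,
                  gt[bad[1]], rownames(gt)[i[1]]))
  }
  alt_count[gt %in% c("0/0", "0|0")] <- 0L
  alt_count[gt %in% c("0/1", "0|1", "1/0", "1|0")] <- 1L
  alt_count[gt %in% c("1/1", "1|1")] <- 2L
  aa <- toupper(aa)
  anc_is_ref <- aa == toupper(fix$REF)
  anc_is_alt <- aa == toupper(fix$ALT)
  if (any(!anc_is_ref & !anc_is_alt)) {
    abort(sprintf("%s: AA allele matches neither REF nor ALT for SNP '%s'",
                  path, fix$ID[which(!anc_is_ref & !anc_is_alt)[1]]))
  }
  dos <- alt_count
  dos[anc_is_ref, ] <- 2L - alt_count[anc_is_ref, , drop = FALSE]
  bind_cols(
    tibble(snp_id = fix$ID,
           chrom_class = chrom_to_class(fix$CHROM),
           position = as.integer(fix$POS),
           ancestral_allele = aa),
    as_tibble(dos))
}

#' Write a genotype table in the native TSV layout
#'
#' @param genotypes A genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, progress = FALSE)
  invisible(path)
}

#' Read a population table
#'
#' Expects a tab-separated file with columns `pop_id`, `latitude`,
#' `individual`: one row per individual. Latitude must be constant within a
#' population and inside \[-90, 90\]; an individual listed under two
#' populations is an error.
#'
#' @param path Input path.
#' @return A population tibble (see [population_table()]).
#' @export
read_populations <- function(path) {
  d <- readr::read_tsv(path, col_types = "cdc", progress = FALSE)
  need <- c("pop_id", "latitude", "individual")
  if (!all(need %in% names(d))) {
    abort(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  lat_chk <- d |> group_by(.data$pop_id) |>
    summarise(n_lat = dplyr::n_distinct(.data$latitude), .groups = "drop")
  if (any(lat_chk$n_lat > 1)) {
    abort(sprintf("%s: population '%s' has more than one latitude", path,
                  lat_chk$pop_id[lat_chk$n_lat > 1][1]))
  }
  pops <- d |> group_by(.data$pop_id) |>
    summarise(latitude = .data$latitude[1],
              members = list(.data$individual), .groups = "drop")
  population_table(pops$pop_id, pops$latitude, pops$members)
}

#' Write a population table
#'
#' @param populations A population tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_populations <- function(populations, path) {
  long <- populations |>
    select("pop_id", "latitude", "members") |>
    tidyr::unnest_longer("members", values_to = "individual")
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; lines starting with `#` are comments; blank lines
#' are ignored; duplicates are removed case-sensitively (symbols differing
#' in case are distinct). An empty list is an error.
#'
#' @param path Input path.
#' @param label List label; defaults to the file name without extension.
#' @return Character vector of unique symbols with a `"label"` attribute.
#' @export
read_gene_list <- function(path, label = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  symbols <- unique(lines)
  if (length(symbols) == 0) {
    abort(sprintf("%s: gene list is empty after removing comments", path))
  }
  inform(sprintf("read %d unique gene symbols from %s", length(symbols), path))
  structure(symbols,
            label = label %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a plain-text gene list
#'
#' @param symbols Character vector of gene symbols.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(symbols, path) {
  writeLines(as.character(symbols), path)
  invisible(path)
}

#' Read / write a SNP annotation table
#'
#' The on-disk layout is TSV with columns `snp_id`, `genes` (comma-joined,
#' empty string for none) and `func_class`.
#'
#' @param path Input or output path.
#' @return For the reader, an annotation tibble (see [snp_annotation()]).
#' @export
read_annotation <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  genes <- strsplit(ifelse(is.na(d$genes), "", d$genes), ",", fixed = TRUE)
  genes <- lapply(genes, function(g) g[nzchar(g)])
  snp_annotation(d$snp_id, genes, d$func_class)
}

#' @rdname read_annotation
#' @param annotation An annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  out <- tibble(
    snp_id = annotation$snp_id,
    genes = purrr::map_chr(annotation$genes, paste, collapse = ","),
    func_class = annotation$func_class)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a key-value run configuration
#'
#' YAML file of scalar keys (quantile, MAF threshold, universe size, seed,
#' paths, ...); used to drive [run_latitude_scan()] reproducibly.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_scan_config <- function(path) {
  yaml::read_yaml(path)
}
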