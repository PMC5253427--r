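#' Diploid genotype table
#'
#' The hub object of the pipeline: a tibble with one row per individual,
#' metadata columns, any number of numeric covariate columns, and two allele
#' columns per microsatellite locus (`<locus>_a1`, `<locus>_a2`, integer
#' allele identifiers, `NA` = missing). Half-calls (one allele observed, one
#' missing) are rejected: microsatellite scoring either resolves both
#' chromosomes or neither.
#'
#' Metadata columns:
#' * `individual_id` — unique label;
#' * `population_id` — local population of sampling (each individual belongs
#'   to exactly one);
#' * `du_id` — designatable unit (conservation unit above the local
#'   population); optional, `NA` allowed;
#' * `behaviour` — `"migratory"`, `"sedentary"` or `"unclassified"`;
#' * `x`, `y` — projected planar coordinates in metres (one shared
#'   projection; no geodesy is done anywhere in the package).
#'
#' @param df data frame with the columns above.
#' @param loci character vector of locus names; if `NULL`, inferred from
#'   paired `_a1`/`_a2` column names.
#' @param require_coords if `TRUE`, all coordinates must be finite (needed
#'   before any distance computation).
#' @return a `genotype_tbl` (tibble subclass) with a `loci` attribute.
#' @export
genotype_table <- function(df, loci = NULL, require_coords = FALSE) {
  df <- tibble::as_tibble(df)
  need <- c("individual_id", "population_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df$individual_id <- as.character(df$individual_id)
  df$population_id <- as.character(df$population_id)
  if (!"du_id" %in% names(df)) df$du_id <- NA_character_
  df$du_id <- as.character(df$du_id)
  if (!"behaviour" %in% names(df)) df$behaviour <- "unclassified"
  if (!"x" %in% names(df)) df$x <- NA_real_
  if (!"y" %in% names(df)) df$y <- NA_real_
  if (is.null(loci)) {
    a1 <- sub("_a1$", "", grep("_a1$", names(df), value = TRUE))
    a2 <- sub("_a2$", "", grep("_a2$", names(df), value = TRUE))
    loci <- intersect(a1, a2)
  }
  if (length(loci) == 0) stop("no loci found (expect <locus>_a1/<locus>_a2 columns)")
  dup <- df$individual_id[duplicated(df$individual_id)]
  if (length(dup)) stop("duplicate individual_id: ", paste(unique(dup), collapse = ", "))
  bad_beh <- setdiff(unique(df$behaviour), c("migratory", "sedentary", "unclassified"))
  if (length(bad_beh)) stop("invalid behaviour label(s): ", paste(bad_beh, collapse = ", "))
  if (length(unique(df$population_id)) < 1 || anyNA(df$population_id)) {
    stop("population_id must be non-missing")
  }
  for (l in loci) {
    c1 <- df[[paste0(l, "_a1")]]; c2 <- df[[paste0(l, "_a2")]]
    if (is.null(c1) || is.null(c2)) stop("locus ", l, " missing an allele column")
    half <- xor(is.na(c1), is.na(c2))
    if (any(half)) {
      stop("half-called genotype at locus ", l, " for individual ",
           df$individual_id[which(half)[1]])
    }
    df[[paste0(l, "_a1")]] <- as.integer(c1)
    df[[paste0(l, "_a2")]] <- as.integer(c2)
  }
  if (require_coords) {
    ok <- is.finite(df$x) & is.finite(df$y)
    if (!all(ok)) {
      stop("non-finite coordinates for individual ", df$individual_id[which(!ok)[1]])
    }
    if (nrow(unique(df[c("x", "y")])) < 2 && nrow(df) >= 2) {
      stop("at least 2 distinct coordinate pairs required for distance operations")
    }
  }
  structure(df, class = c("genotype_tbl", class(tibble::tibble())), loci = loci)
}

#' @rdname genotype_table
#' @param g a `genotype_tbl`.
#' @export
loci <- function(g) attr(g, "loci")

#' @rdname genotype_table
#' @export
n_individuals <- function(g) nrow(g)

#' Allele calls of one locus as an n x 2 integer matrix
#' @keywords internal
locus_alleles <- function(g, locus) {
  cbind(g[[paste0(locus, "_a1")]], g[[paste0(locus, "_a2")]])
}

#' Restrict a genotype table to a behaviour subgroup
#'
#' `"all"` keeps every individual (including unclassified ones);
#' `"migratory"` and `"sedentary"` keep only individuals carrying that label,
#' so unclassified animals are excluded from both behaviour subgroups.
#'
#' @param g a `genotype_tbl`.
#' @param subgroup `"all"`, `"migratory"` or `"sedentary"`.
#' @export
filter_subgroup <- function(g, subgroup = c("all", "migratory", "sedentary")) {
  subgroup <- match.arg(subgroup)
  if (subgroup == "all") return(g)
  out <- g[g$behaviour == subgroup, , drop = FALSE]
  genotype_table(out, loci = loci(g))
}

#' Read genotypes from Genepop or CSV
#'
#' The Genepop dialect accepted is the common 4.x text layout: a title line,
#' locus names (one per line, or a single comma-separated line), `pop`
#' separators, then one line per individual: `name , a1a2 a1a2 ...` with 2- or
#' 3-digit allele codes per gene copy (`00`/`000` = missing). Population
#' blocks are labelled `pop1`, `pop2`, ... in file order. Genepop carries no
#' coordinates or behaviour; those columns come back `NA`/`"unclassified"`.
#'
#' The CSV dialect is the package's own wide layout: metadata columns
#' (`individual_id`, `population_id`, `du_id`, `behaviour`, `x`, `y`),
#' optional numeric covariate columns, then `<locus>_a1`/`<locus>_a2`.
#'
#' @param path file path.
#' @param format `"genepop"` or `"csv"`; default guesses from the extension.
#' @return a validated `genotype_tbl`.
#' @examples
#' # synthetic demo data shipped with the package
#' g <- read_genotypes(system.file("extdata", "demo_genotypes.csv",
#'                                 package = "landgenr"))
#' g
#' @export
read_genotypes <- function(path, format = c("auto", "genepop", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "genepop"
  }
  if (format == "csv") read_genotypes_csv(path) else read_genotypes_genepop(path)
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  genotype_table(df)
}

read_genotypes_genepop <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("Genepop file too short: ", path)
  body <- lines[-1]                       # drop title
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no 'pop' separator found in ", path)
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  locus_names <- unlist(strsplit(paste(locus_lines, collapse = ","), ","))
  locus_names <- trimws(locus_names)
  locus_names <- locus_names[nzchar(locus_names)]
  blocks <- split(
    setdiff(seq_along(body), pop_idx)[setdiff(seq_along(body), pop_idx) > pop_idx[1]],
    findInterval(setdiff(seq_along(body), pop_idx)[setdiff(seq_along(body), pop_idx) > pop_idx[1]], pop_idx)
  )
  rows <- list()
  for (b in seq_along(blocks)) {
    for (i in blocks[[b]]) {
      ln <- body[i]
      if (!grepl(",", ln, fixed = TRUE)) {
        stop("malformed Genepop individual line (no comma) at line ", i + 1, ": ", ln)
      }
      parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
      if (length(codes) != length(locus_names)) {
        stop("line ", i + 1, ": expected ", length(locus_names),
             " genotypes, got ", length(codes))
      }
      al <- lapply(codes, parse_genepop_code, line = i + 1)
      row <- c(list(individual_id = id, population_id = paste0("pop", b)),
               stats::setNames(lapply(al, `[`, 1), paste0(locus_names, "_a1")),
               stats::setNames(lapply(al, `[`, 2), paste0(locus_names, "_a2")))
      rows[[length(rows) + 1]] <- tibble::as_tibble(row)
    }
  }
  genotype_table(dplyr::bind_rows(rows), loci = locus_names)
}

parse_genepop_code <- function(code, line) {
  if (!grepl("^[0-9]+$", code) || !(nchar(code) %in% c(4, 6))) {
    stop("malformed allele code '", code, "' at line ", line)
  }
  w <- nchar(code) / 2
  a <- as.integer(substr(code, 1, w))
  b <- as.integer(substr(code, w + 1, 2 * w))
  if (a == 0 || b == 0) {
    if (a != b) stop("half-missing allele code '", code, "' at line ", line)
    return(c(NA_integer_, NA_integer_))
  }
  c(a, b)
}

#' Write genotypes to Genepop or CSV
#'
#' @param g a `genotype_tbl`.
#' @param path output path.
#' @param format `"genepop"` or `"csv"`.
#' @param digits allele code width for Genepop (2 or 3).
#' @export
write_genotypes <- function(g, path, format = c("csv", "genepop"), digits = 3) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(g), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(digits %in% c(2, 3))
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("genotype table export", con)
  writeLines(loci(g), con)
  for (p in unique(g$population_id)) {
    writeLines("pop", con)
    sub <- g[g$population_id == p, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      codes <- vapply(loci(g), function(l) {
        a <- sub[[paste0(l, "_a1")]][i]; b <- sub[[paste0(l, "_a2")]][i]
        if (is.na(a)) paste0(sprintf(fmt, 0), sprintf(fmt, 0))
        else paste0(sprintf(fmt, a), sprintf(fmt, b))
      }, character(1))
      writeLines(paste0(sub$individual_id[i], " , ", paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Per-population attribute table
#'
#' Census size `n_census` (N_c), effective size `n_effective` (N_e) and the
#' centroid of each local population's range. Sampled individuals are subsets
#' of the census, so no ordering between `n_census` and sample counts is
#' imposed.
#'
#' @param df data frame with columns `population_id`, `n_census`,
#'   `n_effective`, `centroid_x`, `centroid_y`.
#' @export
population_attributes <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("population_id", "n_census", "n_effective", "centroid_x", "centroid_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$n_census <= 0 | df$n_census != round(df$n_census))) {
    stop("n_census must be positive integers")
  }
  if (any(df$n_effective <= 0)) stop("n_effective must be positive")
  if (any(!is.finite(df$centroid_x) | !is.finite(df$centroid_y))) {
    stop("non-finite centroid for population ",
         df$population_id[which(!is.finite(df$centroid_x) | !is.finite(df$centroid_y))[1]])
  }
  df
}

#' @export
print.genotype_tbl <- function(x, ...) {
  cat("<genotype_tbl> ", nrow(x), " individuals, ",
      length(unique(x$population_id)), " populations, ",
      length(attr(x, "loci")), " loci\n", sep = "")
  NextMethod()
}
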