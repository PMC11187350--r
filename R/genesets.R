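#' Named gene set
#'
#' A set of gene symbols with a category tag. Herb target sets and
#' symptom/disease gene sets share this representation; symbols are
#' uppercased, trimmed and unique.
#'
#' @param name set name (e.g. a herb or symptom label).
#' @param members character vector of gene symbols.
#' @param category one of `"herb_target"`, `"symptom_gene"`,
#'   `"disease_gene"`.
#' @return an object of class `gene_set`.
#' @examples
#' gene_set("asthma", c("CASP8", "ERCC2"), "symptom_gene")
#' @export
gene_set <- function(name, members,
                     category = c("symptom_gene", "herb_target",
                                  "disease_gene")) {
  category <- match.arg(category)
  members <- unique(normalize_symbols(members))
  if (length(members) == 0L) {
    stop_input("gene set '", name, "' has no members after normalization")
  }
  structure(list(name = as.character(name), category = category,
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "' (", x$category, "): ",
      length(x$members), " members\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members, tab-separated. The
#' description field carries the category when it matches a known category
#' name; anything else is stored as `"symptom_gene"` unless it contains
#' `"target"`. Duplicate members within a line are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of [gene_set()] objects (possibly empty).
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_input("gene-set file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  sets <- list()
  n_dups <- 0L
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_input("GMT parse error: line ", i, " has fewer than 3 fields")
    }
    members <- normalize_symbols(f[-(1:2)])
    n_dups <- n_dups + (length(members) - length(unique(members)))
    members <- unique(members)
    if (length(members) == 0L) {
      stop_input("GMT validation error: set '", f[1L],
                 "' on line ", i, " has no members")
    }
    desc <- tolower(trimws(f[2L]))
    category <- if (desc %in% c("herb_target", "symptom_gene",
                                "disease_gene")) {
      desc
    } else if (grepl("target", desc)) "herb_target" else "symptom_gene"
    gs <- gene_set(f[1L], members, category)
    sets[[gs$name]] <- gs
  }
  if (n_dups > 0L) {
    warning(n_dups, " duplicate member(s) dropped while reading ", path)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gene_sets_gmt()]; members are written in their stored
#' order, the category in the description column.
#'
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$category, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
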