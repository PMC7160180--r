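#' Read a rooted, time-calibrated phylogeny
#'
#' Reads a Newick tree with branch lengths in Myr, checks structural
#' invariants (unique tip labels, non-negative branch lengths, presence of
#' branch lengths), reports polytomies, and optionally enforces
#' ultrametricity to within a relative tolerance of 1e-6.
#'
#' @param path Path to a Newick file.
#' @param ultrametric If `TRUE`, refuse trees whose root-to-tip path lengths
#'   differ by more than 1e-6 relative tolerance. Diversification statistics
#'   (the gamma statistic in particular) are only defined on ultrametric
#'   trees, so callers feeding those analyses should set this.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path, ultrametric = FALSE) {
  if (!file.exists(path)) abort(paste0("Tree file not found: ", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("Unreadable Newick file: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("Unreadable Newick file (no tree parsed).")
  validate_phylogeny(tree, ultrametric = ultrametric)
}

#' Validate a phylogeny against the package's structural invariants
#'
#' @param tree An [ape::phylo] object.
#' @inheritParams read_tree
#' @return The tree, invisibly modified only by whitespace-trimming of tip
#'   labels.
#' @export
validate_phylogeny <- function(tree, ultrametric = FALSE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object.")
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths.")
  if (anyNA(tree$edge.length)) abort("Tree has missing branch lengths.")
  if (any(tree$edge.length < 0)) abort("Tree has negative branch lengths.")
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("Duplicate tip labels: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (ultrametric && !is_ultrametric_tree(tree)) {
    abort("Tree declared ultrametric but root-to-tip path lengths differ by more than 1e-6 relative tolerance.")
  }
  if (!ape::is.binary.phylo(tree)) {
    n_poly <- sum(tabulate(tree$edge[, 1]) > 2)
    inform(paste0("Tree contains ", n_poly,
                  " polytomies; contrasts will be undefined at those nodes."))
  }
  tree
}

#' Write a phylogeny to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a tip-by-host incidence table
#'
#' Accepts either a long table with columns `taxon`, `host` (one row per
#' association) or a wide 0/1 incidence matrix whose first column is the
#' taxon and whose remaining columns are host taxa. Both dialects parse to
#' the same mapping. Taxon and host names are whitespace-trimmed; matching
#' elsewhere in the package is exact string matching (no fuzzy matching —
#' silent mismatches are worse than hard errors).
#'
#' @param path Path to a TSV or CSV file (delimiter inferred from extension;
#'   `.csv` means comma, anything else tab).
#' @param format `"long"` or `"wide"`.
#' @return A named list mapping taxon to a character vector of host taxa.
#'   Taxa whose host set is empty are kept with a zero-length entry and
#'   carry the attribute `"empty_taxa"` listing them; downstream validation
#'   flags them for exclusion.
#' @export
read_host_table <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Host table not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (format == "long") {
    names(df) <- tolower(names(df))
    if (!all(c("taxon", "host") %in% names(df))) {
      abort("Long host table must have columns 'taxon' and 'host'.")
    }
    host_table_from_long(df)
  } else {
    host_table_from_wide(df)
  }
}

host_table_from_long <- function(df) {
  taxon <- trimws(as.character(df$taxon))
  host <- trimws(as.character(df$host))
  keep <- !is.na(host) & host != ""
  tab <- split(host[keep], taxon[keep])
  tab <- lapply(tab, function(h) sort(unique(h)))
  # Taxa present only with empty host entries are retained empty and flagged.
  empties <- setdiff(unique(taxon), names(tab))
  for (t in empties) tab[[t]] <- character(0)
  tab <- tab[order(names(tab))]
  structure(tab, empty_taxa = empties)
}

host_table_from_wide <- function(df) {
  taxon <- trimws(as.character(df[[1]]))
  if (anyDuplicated(taxon)) abort("Wide host table has duplicate taxa.")
  hosts <- trimws(names(df)[-1])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  if (any(!mat %in% c(0, 1))) abort("Wide host table must contain only 0/1 values.")
  tab <- lapply(seq_along(taxon), function(i) sort(hosts[mat[i, ] == 1]))
  names(tab) <- taxon
  empties <- taxon[lengths(tab) == 0]
  tab <- tab[order(names(tab))]
  structure(tab, empty_taxa = empties)
}

#' Coerce a host mapping to a long tibble
#'
#' @param hosts A named list mapping taxon to host vectors.
#' @return A tibble with columns `taxon`, `host`.
#' @export
host_table_to_long <- function(hosts) {
  tibble::tibble(
    taxon = rep(names(hosts), lengths(hosts)),
    host = unlist(hosts, use.names = FALSE) %||% character(0)
  )
}

#' Read a tip richness table
#'
#' @param path TSV/CSV with columns `taxon` and `richness` (extant species
#'   count per tip taxon, a positive integer).
#' @return A named integer vector of species counts.
#' @export
read_richness_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Richness table not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("taxon", "richness") %in% names(df))) {
    abort("Richness table must have columns 'taxon' and 'richness'.")
  }
  rich <- as.integer(df$richness)
  if (anyNA(rich) || any(rich < 1)) {
    abort("Richness counts must be integers >= 1.")
  }
  setNames(rich, trimws(as.character(df$taxon)))
}

#' Read a host metadata table
#'
#' @param path TSV/CSV with columns `host`, `stem_age` (Myr, > 0) and
#'   `diversity` (extant species count, >= 1). Stem ages and diversities are
#'   inputs here (in the motivating application they come from time-tree and
#'   species-catalogue databases); no online lookup is performed.
#' @return A tibble with columns `host`, `stem_age`, `diversity`.
#' @export
read_host_meta <- function(path) {
  if (!file.exists(path)) abort(paste0("Host metadata table not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("host", "stem_age", "diversity") %in% names(df))) {
    abort("Host metadata must have columns 'host', 'stem_age', 'diversity'.")
  }
  out <- tibble::tibble(
    host = trimws(as.character(df$host)),
    stem_age = as.numeric(df$stem_age),
    diversity = as.numeric(df$diversity)
  )
  if (any(out$stem_age <= 0)) abort("Host stem ages must be > 0.")
  if (any(out$diversity < 1)) abort("Host diversities must be >= 1.")
  out
}

#' Validate a dataset against a tree without mutating anything
#'
#' Cross-checks a phylogeny against host, richness and metadata tables and
#' reports (without dropping anything itself): tips lacking host data, tips
#' whose host breadth exceeds a cap, hosts used by fewer taxa than a
#' threshold, and tips missing richness entries. Filtering is performed
#' explicitly by [filter_hosts()] and [apply_breadth_cap()].
#'
#' @param tree An [ape::phylo] object.
#' @param hosts Named list mapping taxon to host vectors.
#' @param richness Optional named integer vector of species counts.
#' @param breadth_cap Maximum host breadth; tips above it are listed.
#' @param min_host_users Hosts used by fewer than this many taxa are listed.
#' @return An object of class `hostshift_validation`: a list with elements
#'   `n_tips`, `tips_without_hosts`, `tips_over_breadth`, `rare_hosts`,
#'   `tips_without_richness`, `ok`.
#' @export
validate_dataset <- function(tree, hosts, richness = NULL,
                             breadth_cap = Inf, min_host_users = 1L) {
  tips <- tree$tip.label
  covered <- names(hosts)[lengths(hosts) > 0]
  no_hosts <- sort(setdiff(tips, covered))
  breadth <- lengths(hosts)[intersect(tips, names(hosts))]
  over <- sort(names(breadth)[breadth > breadth_cap])
  long <- host_table_to_long(hosts[intersect(tips, names(hosts))])
  users <- table(long$host)
  rare <- sort(names(users)[users < min_host_users])
  no_rich <- character(0)
  if (!is.null(richness)) no_rich <- sort(setdiff(tips, names(richness)))
  out <- list(
    n_tips = length(tips),
    tips_without_hosts = no_hosts,
    tips_over_breadth = over,
    rare_hosts = rare,
    tips_without_richness = no_rich,
    ok = length(no_hosts) == 0 && length(over) == 0 && length(rare) == 0 &&
      length(no_rich) == 0
  )
  class(out) <- "hostshift_validation"
  out
}

#' @export
print.hostshift_validation <- function(x, ...) {
  cat("Dataset validation (", x$n_tips, " tips)\n", sep = "")
  cat("  tips without host data:  ", length(x$tips_without_hosts), "\n")
  cat("  tips over breadth cap:   ", length(x$tips_over_breadth), "\n")
  cat("  hosts below user count:  ", length(x$rare_hosts), "\n")
  cat("  tips without richness:   ", length(x$tips_without_richness), "\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report A `hostshift_validation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
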