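#' Study configuration
#'
#' A study configuration holds the species panel (name, ploidy, tolerance
#' phenotype), the analysis thresholds, and the expansion hypotheses. It is
#' the single object every other stage of the pipeline consults for species
#' order, ploidy correction and significance cutoffs.
#'
#' @param species character vector of species names (length >= 2).
#' @param ploidy integer vector of ploidies, one per species. Must be even
#'   and >= 2; 2 is the diploid baseline. A tetraploid's raw gene counts are
#'   halved before expansion calls.
#' @param phenotype character vector, one per species, each either
#'   `"tolerant"` or `"sensitive"`. Both classes must be non-empty.
#' @param alpha_de adjusted-p cutoff for calling a gene differentially
#'   expressed (inclusive). Default 0.1.
#' @param alpha_sel corrected-p cutoff for calling diversifying selection
#'   (inclusive). Default 0.05.
#' @param expansion_factor fold threshold for expansion: the focal species
#'   must have at least this multiple of every background species'
#'   ploidy-corrected count. Default 2.
#' @param min_focal_copies minimum raw copy number in the focal species for
#'   an expansion call ("expansion" implies duplication). Set to 1 to apply
#'   the bare fold inequality. Default 2.
#' @param hypotheses list of hypotheses from [hypothesis()], or `NULL` to
#'   derive the default panel with [default_hypotheses()].
#'
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config(
#'   species   = c("tolA", "tolB", "senA", "senB"),
#'   ploidy    = c(2, 2, 2, 4),
#'   phenotype = c("tolerant", "tolerant", "sensitive", "sensitive")
#' )
#' @export
study_config <- function(species, ploidy, phenotype,
                         alpha_de = 0.1, alpha_sel = 0.05,
                         expansion_factor = 2, min_focal_copies = 2,
                         hypotheses = NULL) {
  species <- as.character(species)
  if (length(species) < 2L) stop("need at least 2 species")
  if (anyDuplicated(species)) stop("duplicated species name")
  if (length(ploidy) != length(species) || length(phenotype) != length(species))
    stop("ploidy and phenotype must have one entry per species")
  ploidy <- as.integer(ploidy)
  if (any(is.na(ploidy)) || any(ploidy < 2L) || any(ploidy %% 2L != 0L))
    stop("ploidy must be an even integer >= 2")
  phenotype <- match.arg(phenotype, c("tolerant", "sensitive"),
                         several.ok = TRUE)
  phenotype <- as.character(phenotype)
  if (length(phenotype) != length(species))
    stop("phenotype must be 'tolerant' or 'sensitive', one per species")
  if (!all(c("tolerant", "sensitive") %in% phenotype))
    stop("both phenotype classes must be non-empty")
  for (a in c(alpha_de, alpha_sel))
    if (!is.numeric(a) || a <= 0 || a >= 1) stop("alpha values must be in (0,1)")
  if (expansion_factor <= 0) stop("expansion_factor must be positive")
  if (min_focal_copies < 1) stop("min_focal_copies must be >= 1")

  cfg <- structure(
    list(
      species = data.frame(name = species, ploidy = ploidy,
                           phenotype = phenotype, stringsAsFactors = FALSE),
      alpha_de = alpha_de, alpha_sel = alpha_sel,
      expansion_factor = expansion_factor,
      min_focal_copies = as.integer(min_focal_copies),
      hypotheses = NULL
    ),
    class = "study_config"
  )
  cfg$hypotheses <- if (is.null(hypotheses)) default_hypotheses(cfg) else {
    lapply(hypotheses, validate_hypothesis, species = species)
  }
  names(cfg$hypotheses) <- vapply(cfg$hypotheses, `[[`, "", "id")
  cfg
}

#' Expansion hypothesis
#'
#' A hypothesis names the focal species that must all be expanded relative
#' to every background species. Focal and background sets must be disjoint
#' and non-empty.
#'
#' @param id short identifier used in result tables.
#' @param focal character vector of focal species (each must be expanded).
#' @param background character vector of contrasted background species.
#' @param factor fold threshold; defaults to the config's value when used
#'   through [expansion_matrix()].
#' @return A list of class `hypothesis`.
#' @export
hypothesis <- function(id, focal, background, factor = NULL) {
  h <- structure(list(id = as.character(id), focal = as.character(focal),
                      background = as.character(background), factor = factor),
                 class = "hypothesis")
  if (length(h$focal) == 0L || length(h$background) == 0L)
    stop("hypothesis '", id, "': focal and background must be non-empty")
  if (length(intersect(h$focal, h$background)))
    stop("hypothesis '", id, "': focal and background overlap")
  h
}

validate_hypothesis <- function(h, species) {
  if (!inherits(h, "hypothesis")) h <- do.call(hypothesis, h)
  unknown <- setdiff(c(h$focal, h$background), species)
  if (length(unknown))
    stop("hypothesis '", h$id, "': unknown species ", paste(unknown, collapse = ", "))
  h
}

#' Default hypothesis panel
#'
#' Builds the standard contrast panel from the phenotype labels: one
#' hypothesis per species against all species of the opposite phenotype,
#' plus one joint hypothesis per phenotype class requiring expansion in
#' every member of the class.
#'
#' @param config a `study_config` (its `hypotheses` field is ignored).
#' @return Named list of `hypothesis` objects. Per-species hypotheses are
#'   named after the species; joint ones `both_tolerant` / `both_sensitive`
#'   (or `all_*` when a class has more than two members).
#' @export
default_hypotheses <- function(config) {
  sp <- config$species
  tol <- sp$name[sp$phenotype == "tolerant"]
  sen <- sp$name[sp$phenotype == "sensitive"]
  hs <- list()
  for (s in tol) hs[[s]] <- hypothesis(s, s, sen)
  for (s in sen) hs[[s]] <- hypothesis(s, s, tol)
  lab <- function(class, n) if (n > 2) paste0("all_", class) else paste0("both_", class)
  hs[[lab("tolerant", length(tol))]] <-
    hypothesis(lab("tolerant", length(tol)), tol, sen)
  hs[[lab("sensitive", length(sen))]] <-
    hypothesis(lab("sensitive", length(sen)), sen, tol)
  hs
}

#' @export
print.study_config <- function(x, ...) {
  cat("study_config:", nrow(x$species), "species\n")
  print(x$species, row.names = FALSE)
  cat(sprintf("alpha_de=%g alpha_sel=%g expansion_factor=%g min_focal_copies=%d\n",
              x$alpha_de, x$alpha_sel, x$expansion_factor, x$min_focal_copies))
  cat("hypotheses:", paste(names(x$hypotheses), collapse = ", "), "\n")
  invisible(x)
}

species_of <- function(config, phenotype) {
  config$species$name[config$species$phenotype == phenotype]
}

ploidy_vector <- function(config) {
  stats::setNames(config$species$ploidy, config$species$name)
}

#' Read / write a study configuration file
#'
#' The on-disk format is a small YAML document with a `species` list (each
#' entry `name`, `ploidy`, `phenotype`) and optional scalar keys `alpha_de`,
#' `alpha_sel`, `expansion_factor`, `min_focal_copies`, and an optional
#' `hypotheses` list (each entry `id`, `focal`, `background`).
#'
#' @param path file path.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species)) stop("config: missing 'species' section")
  sp <- do.call(rbind, lapply(doc$species, function(s)
    data.frame(name = s$name, ploidy = s$ploidy, phenotype = s$phenotype,
               stringsAsFactors = FALSE)))
  hyp <- NULL
  if (!is.null(doc$hypotheses))
    hyp <- lapply(doc$hypotheses, function(h)
      hypothesis(h$id, h$focal, h$background))
  args <- list(species = sp$name, ploidy = sp$ploidy, phenotype = sp$phenotype,
               hypotheses = hyp)
  for (k in c("alpha_de", "alpha_sel", "expansion_factor", "min_focal_copies"))
    if (!is.null(doc[[k]])) args[[k]] <- doc[[k]]
  do.call(study_config, args)
}

#' @rdname read_study_config
#' @param config a `study_config`.
#' @export
write_study_config <- function(config, path) {
  doc <- list(
    species = lapply(seq_len(nrow(config$species)), function(i)
      as.list(config$species[i, , drop = FALSE])),
    alpha_de = config$alpha_de, alpha_sel = config$alpha_sel,
    expansion_factor = config$expansion_factor,
    min_focal_copies = config$min_focal_copies,
    hypotheses = lapply(unname(config$hypotheses), function(h)
      list(id = h$id, focal = h$focal, background = h$background))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
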