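# The clade-contrast engine: contrast scheme, percentage-difference
# signatures with arrow classes, significance annotation, tree leaf-depth
# check, habitat summaries and NMDS ordination.

#' Clade scheme: isolate-clade mapping and ordered contrasts
#'
#' Bundles the isolate-to-clade mapping with the ordered list of contrasts
#' (target clade, reference clade, adaptation label). The default contrasts
#' follow the standard poly-extremophile design: psychrophilic Ib vs Ia,
#' halophilic IIa vs Ia, thermophilic IIb vs IIa.
#'
#' @param clades Tibble with `isolate_id`, `clade`.
#' @param contrasts Tibble with `target`, `reference`, `label`; defaults to
#'   [default_contrasts()].
#' @return List of class `clade_scheme` with elements `clades`, `contrasts`.
#' @export
clade_scheme <- function(clades, contrasts = default_contrasts()) {
  stopifnot(all(c("isolate_id", "clade") %in% names(clades)),
            all(c("target", "reference", "label") %in% names(contrasts)))
  missing_clades <- setdiff(c(contrasts$target, contrasts$reference), clades$clade)
  if (length(missing_clades) > 0) {
    abort(paste0("contrast clade(s) absent from mapping: ",
                 paste(missing_clades, collapse = ", ")))
  }
  structure(list(clades = tibble::as_tibble(clades),
                 contrasts = tibble::as_tibble(contrasts)),
            class = "clade_scheme")
}

#' @rdname clade_scheme
#' @export
default_contrasts <- function() {
  tibble::tibble(
    target = c("Ib", "IIa", "IIb"),
    reference = c("Ia", "Ia", "IIa"),
    label = c("psychrophilic", "halophilic", "thermophilic")
  )
}

#' Arrow class of a percentage difference
#'
#' Discretises a percentage difference `d` given its significance: `-` when
#' p > .05 or |d| < 1; a double arrow when |d| >= 5 (boundary inclusive) in
#' the sign of d; a single arrow for 1 <= |d| < 5.
#'
#' @param d Percentage differences.
#' @param p Test p-values.
#' @return Character vector over `{"up2","up","none","down","down2"}` rendered
#'   as arrows; missing d gives `NA`.
#' @export
#' @examples
#' arrow_class(c(6, -3, 8), c(0.001, 0.001, 0.2))
arrow_class <- function(d, p) {
  dplyr::case_when(
    is.na(d) ~ NA_character_,
    is.na(p) | p > 0.05 | abs(d) < 1 ~ "-",
    d >= 5 ~ "↑↑",
    d >= 1 ~ "↑",
    d <= -5 ~ "↓↓",
    TRUE ~ "↓"
  )
}

#' Run clade contrasts over a feature table
#'
#' For every contrast of the scheme and every feature: clade means, the
#' percentage difference `d = 100 (mean_target - mean_ref)/mean_ref`, a
#' two-sample test p-value ([rank_contrast()] on per-isolate values or
#' [ks_contrast()] on per-protein values), the arrow and star classes, and a
#' Benjamini-Hochberg adjusted p across features within the contrast (raw p
#' retained and used for arrows/stars).
#'
#' @param data Long tibble with columns `id` (isolate or protein), `clade`,
#'   `feature`, `value`.
#' @param scheme A [clade_scheme()].
#' @param test `"rank"` (Wilcoxon rank-sum) or `"ks"` (Kolmogorov-Smirnov).
#' @return A `signature_report` tibble: `label`, `target`, `reference`,
#'   `feature`, `mean_target`, `mean_reference`, `d`, `p_value`, `p_adj`,
#'   `star`, `arrow`, `n_target`, `n_reference`.
#' @export
run_contrasts <- function(data, scheme, test = c("rank", "ks")) {
  test <- match.arg(test)
  stopifnot(all(c("clade", "feature", "value") %in% names(data)))
  rows <- purrr::pmap_dfr(scheme$contrasts, function(target, reference, label) {
    dt <- data[data$clade == target, ]
    dr <- data[data$clade == reference, ]
    if (nrow(dt) == 0) abort(paste0("contrast clade absent from data: ", target))
    if (nrow(dr) == 0) abort(paste0("contrast clade absent from data: ", reference))
    feats <- sort(unique(data$feature))
    res <- purrr::map_dfr(feats, function(ft) {
      xt <- dt$value[dt$feature == ft]
      xr <- dr$value[dr$feature == ft]
      xt <- xt[!is.na(xt)]; xr <- xr[!is.na(xr)]
      mt <- if (length(xt)) mean(xt) else NA_real_
      mr <- if (length(xr)) mean(xr) else NA_real_
      d <- if (!is.na(mr) && mr != 0) 100 * (mt - mr) / mr else NA_real_
      p <- NA_real_
      enough <- if (test == "rank") {
        length(xt) >= 2 && length(xr) >= 2
      } else {
        length(xt) >= 5 && length(xr) >= 5
      }
      if (enough) {
        if (identical(xt, xr) || (length(unique(c(xt, xr))) == 1)) {
          p <- 1
        } else if (test == "rank") {
          p <- rank_contrast(xt, xr)$p_value
        } else {
          p <- ks_contrast(xt, xr)$p_value
        }
      }
      tibble::tibble(feature = ft, mean_target = mt, mean_reference = mr,
                     d = d, p_value = p,
                     n_target = length(xt), n_reference = length(xr))
    })
    res$p_adj <- p.adjust(res$p_value, method = "BH")
    dplyr::mutate(res, label = label, target = target, reference = reference,
                  .before = 1)
  })
  rows <- dplyr::mutate(rows,
                        star = star_class(.data$p_value),
                        arrow = arrow_class(.data$d, .data$p_value))
  class(rows) <- c("signature_report", class(rows))
  rows
}

#' Mean root-to-leaf depth per clade
#'
#' Sum of branch lengths from the root to each clade member leaf, averaged
#' per clade. A flag is raised when any clade mean is at or above
#' `flag_depth` (deep leaves suggest uneven evolutionary distances between
#' the units being contrasted).
#'
#' @param tree An [ape::phylo] tree whose tips are isolate ids.
#' @param scheme A [clade_scheme()] (or a tibble `isolate_id` -> `clade`).
#' @param flag_depth Depth threshold for the flag.
#' @return Tibble with `clade`, `mean_depth`, `n`, `flag`.
#' @export
clade_leaf_depth <- function(tree, scheme, flag_depth = 0.5) {
  clades <- if (inherits(scheme, "clade_scheme")) scheme$clades else scheme
  missing_tips <- setdiff(clades$isolate_id, tree$tip.label)
  if (length(missing_tips) > 0) {
    abort(paste0("isolate(s) not in tree: ", paste(missing_tips, collapse = ", ")))
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depths) <- tree$tip.label
  clades |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(mean_depth = mean(depths[.data$isolate_id]),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(flag = .data$mean_depth >= flag_depth)
}

#' Habitat summary per clade
#'
#' Mean isolation-site temperature (MAT) and salinity per clade, with missing
#' values excluded and the number of observations reported per cell, plus the
#' same summary at the major-clade level (subclade labels collapsed with
#' `major_rule`).
#'
#' @param metadata Tibble with `isolate_id`, `clade_label`, and `MAT` and/or
#'   `salinity`.
#' @param major_rule Function collapsing a subclade label to its major clade;
#'   the default strips a trailing lowercase letter (Ib -> I).
#' @return List of tibbles `subclades` and `major_clades`, each with per-clade
#'   `mean_MAT`, `n_MAT`, `mean_salinity`, `n_salinity`.
#' @export
habitat_summary <- function(metadata,
                            major_rule = function(x) sub("[a-z]+$", "", x)) {
  summarise_by <- function(md, group) {
    out <- md |>
      dplyr::group_by(clade = .data[[group]]) |>
      dplyr::summarise(
        mean_MAT = if (sum(!is.na(.data$MAT)) > 0) mean(.data$MAT, na.rm = TRUE) else NA_real_,
        n_MAT = sum(!is.na(.data$MAT)),
        mean_salinity = if (sum(!is.na(.data$salinity)) > 0) {
          mean(.data$salinity, na.rm = TRUE)
        } else {
          NA_real_
        },
        n_salinity = sum(!is.na(.data$salinity)),
        .groups = "drop")
    if (any(out$n_MAT == 0) || any(out$n_salinity == 0)) {
      warn("clade(s) with all-missing habitat values")
    }
    out
  }
  md <- metadata
  if (!"MAT" %in% names(md)) md$MAT <- NA_real_
  if (!"salinity" %in% names(md)) md$salinity <- NA_real_
  md$major <- major_rule(md$clade_label)
  list(subclades = summarise_by(md, "clade_label"),
       major_clades = summarise_by(md, "major"))
}

#' Non-metric multidimensional scaling of a feature matrix
#'
#' NMDS ordination (Kruskal stress, monotone regression) of isolates in
#' feature space, via multiple seeded random restarts with the best stress
#' retained; coordinates are centred.
#'
#' @param feature_table Tibble with `isolate_id` and numeric feature columns.
#' @param distance `"bray_curtis"` (non-negative features) or `"euclidean"`.
#' @param k Target dimension.
#' @param seed RNG seed for the restarts.
#' @param trymax Number of random restarts.
#' @return List of class `ecosig_ordination`: `points` (tibble `isolate_id`,
#'   `NMDS1`..), `stress`, `distance`.
#' @export
ordinate_features <- function(feature_table, distance = c("bray_curtis", "euclidean"),
                              k = 2, seed = 1, trymax = 10) {
  distance <- match.arg(distance)
  m <- as.matrix(feature_table[, setdiff(names(feature_table), "isolate_id")])
  rownames(m) <- feature_table$isolate_id
  if (nrow(m) < k + 1) abort("need at least k+1 rows for ordination")
  if (all(apply(m, 2, function(x) length(unique(x)) == 1))) {
    abort("zero variance: all rows identical")
  }
  d <- if (distance == "bray_curtis") {
    if (any(m < 0)) abort("bray_curtis needs non-negative entries")
    vegan::vegdist(m, method = "bray")
  } else {
    dist(m)
  }
  if (any(!is.finite(d)) || max(d) == 0) abort("zero variance: all rows identical")
  fit <- withr::with_seed(seed, vegan::metaMDS(d, k = k, trymax = trymax,
                                               trace = 0, autotransform = FALSE,
                                               wascores = FALSE))
  pts <- scale(vegan::scores(fit, display = "sites"), scale = FALSE)
  out <- tibble::as_tibble(pts)
  names(out) <- paste0("NMDS", seq_len(ncol(out)))
  out <- dplyr::bind_cols(tibble::tibble(isolate_id = rownames(m)), out)
  structure(list(points = out, stress = fit$stress, distance = distance),
            class = "ecosig_ordination")
}
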