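#' @title Lipidomic adaptation: TLC fractions, saturation pairs, flux ratios
#' @name lipidomics
#' @description Species-level lipid intensity tables (long format:
#'   class, total acyl carbons, double bonds, label state, sample,
#'   intensity) are summarized three ways: fraction-of-total per
#'   TLC lane; saturation-pair remodeling fractions quantifying the
#'   cold-induced shift from saturated to mono- and from mono- to
#'   di-unsaturated species; and stable-isotope labeling ratios along
#'   the PS -> PE -> PC synthesis chain that separate conversion and
#'   transport efficiency from absolute label uptake.
NULL

#' Read a long-format lipid species table
#'
#' Expected tab-separated columns: `class`, `carbons`, `double_bonds`,
#' `label` (unlabeled / 15N), `sample`, `intensity`; optional `group`
#' and `timepoint`. Odd or short (< 20) total acyl carbon numbers are
#' unusual for yeast glycerophospholipids and trigger a warning, not an
#' error.
#'
#' @param path TSV path.
#' @return the validated data.frame.
#' @export
read_lipid_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_lipid_table(df)
}

#' @rdname read_lipid_table
#' @param table a data.frame built in code rather than read from disk.
#' @export
validate_lipid_table <- function(table) {
  need <- c("class", "carbons", "double_bonds", "label", "sample",
            "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("lipid table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$intensity < 0)) stop("negative intensity")
  if (any(table$double_bonds < 0)) stop("negative double bond count")
  odd <- table$carbons %% 2 != 0 | table$carbons < 20
  if (any(odd))
    warning(sum(odd), " species with odd or < 20 total acyl carbons")
  table
}

#' Parse "CLASS C:D" species names
#'
#' e.g. "PE 34:2" -> class PE, 34 carbons, 2 double bonds. Names that do
#' not follow the pattern (ether lipids etc.) return NA fields.
#'
#' @param x character vector of species names.
#' @return data.frame with `class`, `carbons`, `double_bonds`.
#' @export
parse_species_name <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z]+) ([0-9]+):([0-9]+)$", x))
  out <- data.frame(
    class = vapply(m, function(z) if (length(z)) z[2L] else NA_character_,
                   ""),
    carbons = vapply(m, function(z)
      if (length(z)) as.integer(z[3L]) else NA_integer_, 0L),
    double_bonds = vapply(m, function(z)
      if (length(z)) as.integer(z[4L]) else NA_integer_, 0L),
    stringsAsFactors = FALSE)
  out
}

#' Fraction of total lipid per TLC lane
#'
#' Each species' quantity divided by the lane total, the standard
#' readout for thin-layer chromatography quantification.
#'
#' @param lane_quantities named non-negative numeric vector (one lane).
#' @return named fractions summing to 1.
#' @export
tlc_fractions <- function(lane_quantities) {
  if (any(lane_quantities < 0)) stop("negative lane quantity")
  total <- sum(lane_quantities)
  if (total == 0) stop("all-zero lane")
  lane_quantities / total
}

#' Classify a species into the saturation comparison pair
#'
#' The remodeling readout compares 0- vs 1-double-bond species for
#' lipids with <= 30 total acyl carbons, and 1- vs 2-double-bond species
#' for lipids with >= 32 carbons. Species outside these pairs (including
#' 31-carbon odd chains) are classified `outside_pair`.
#'
#' @param carbons,double_bonds integer vectors (recycled to a common
#'   length).
#' @return character vector: "less_unsaturated", "more_unsaturated", or
#'   "outside_pair".
#' @export
classify_saturation_pair <- function(carbons, double_bonds) {
  n <- max(length(carbons), length(double_bonds))
  carbons <- rep_len(carbons, n); double_bonds <- rep_len(double_bonds, n)
  out <- rep("outside_pair", n)
  out[carbons <= 30 & double_bonds == 0] <- "less_unsaturated"
  out[carbons <= 30 & double_bonds == 1] <- "more_unsaturated"
  out[carbons >= 32 & double_bonds == 1] <- "less_unsaturated"
  out[carbons >= 32 & double_bonds == 2] <- "more_unsaturated"
  out
}

#' Saturation-pair remodeling fractions
#'
#' Per lipid class and sample, the share of the pair total carried by
#' the more-unsaturated members:
#' `frac = sum(intensity[more]) / (sum(more) + sum(less))`,
#' pooling the <= 30-carbon and >= 32-carbon pairs within the class
#' (weighted by intensity) so one number summarizes each class per
#' sample. Set `pool_carbons = FALSE` for per-carbon-group fractions.
#' Samples lacking both pair members get `NA`, never 0, to avoid
#' biasing remodeling estimates. When the table carries a `group`
#' column, every pair of groups is compared per class with a two-sided
#' two-sample Student's t-test over the replicate fractions; groups with
#' fewer than two replicates yield `NA` p-values.
#'
#' @param table long-format lipid table (unlabeled species only are
#'   used if a `label` column is present).
#' @param pool_carbons pool the two carbon-range pairs (default TRUE).
#' @return list with `fractions` (class, sample, group, carbon_range,
#'   frac_more_unsaturated, pair_total) and `comparisons` (class,
#'   group_a, group_b, mean_a, mean_b, difference, p_value) or NULL
#'   when no `group` column is present.
#' @export
saturation_fractions <- function(table, pool_carbons = TRUE) {
  table <- validate_lipid_table(table)
  if ("label" %in% names(table))
    table <- table[table$label == "unlabeled", , drop = FALSE]
  memb <- classify_saturation_pair(table$carbons, table$double_bonds)
  tab <- table[memb != "outside_pair", , drop = FALSE]
  memb <- memb[memb != "outside_pair"]
  if (!nrow(tab)) stop("no species fall in a saturation pair")
  tab$carbon_range <- ifelse(tab$carbons <= 30, "le30C", "ge32C")
  if (pool_carbons) tab$carbon_range <- "pooled"
  has_group <- "group" %in% names(tab)
  if (!has_group) tab$group <- "all"

  tab$.more <- tab$intensity * (memb == "more_unsaturated")
  agg <- stats::aggregate(cbind(more = .more, tot = intensity) ~
                            class + sample + group + carbon_range,
                          data = tab, FUN = sum, na.action = stats::na.pass)
  fr <- data.frame(class = agg$class, sample = agg$sample,
                   group = agg$group, carbon_range = agg$carbon_range,
                   frac_more_unsaturated =
                     ifelse(agg$tot > 0, agg$more / agg$tot, NA_real_),
                   pair_total = agg$tot,
                   stringsAsFactors = FALSE)
  fr <- fr[order(fr$class, fr$sample), , drop = FALSE]
  rownames(fr) <- NULL

  comparisons <- NULL
  if (has_group) {
    rows <- list()
    for (cl in unique(fr$class)) {
      for (cr in unique(fr$carbon_range)) {
        sub <- fr[fr$class == cl & fr$carbon_range == cr &
                    !is.na(fr$frac_more_unsaturated), , drop = FALSE]
        grps <- sort(unique(sub$group))
        if (length(grps) < 2L) next
        for (i in seq_len(length(grps) - 1L)) for (j in (i + 1L):length(grps)) {
          fa <- sub$frac_more_unsaturated[sub$group == grps[i]]
          fb <- sub$frac_more_unsaturated[sub$group == grps[j]]
          p <- if (length(fa) >= 2L && length(fb) >= 2L &&
                   (stats::sd(fa) > 0 || stats::sd(fb) > 0))
            stats::t.test(fa, fb, var.equal = TRUE)$p.value
          else if (length(fa) >= 2L && length(fb) >= 2L &&
                   mean(fa) == mean(fb)) 1
          else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            class = cl, carbon_range = cr,
            group_a = grps[i], group_b = grps[j],
            mean_a = mean(fa), mean_b = mean(fb),
            difference = mean(fa) - mean(fb), p_value = p,
            stringsAsFactors = FALSE)
        }
      }
    }
    comparisons <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(fractions = fr, comparisons = comparisons)
}

#' Per-species abundance shares within each lipid class
#'
#' Within each class and sample, a species' share is its intensity
#' divided by the class total, making shares invariant to global
#' intensity rescaling. When a `group` column with exactly two groups is
#' present (or `compare` names two groups), group mean shares and
#' per-species two-sided Student's t-tests are reported.
#'
#' @param table long-format lipid table (unlabeled species if labeled).
#' @param compare optional length-2 character vector of group labels.
#' @return list with `shares` (class, carbons, double_bonds, sample,
#'   group, share) and `tests` (per-species group comparison) or NULL.
#' @export
per_species_abundance_grid <- function(table, compare = NULL) {
  table <- validate_lipid_table(table)
  if ("label" %in% names(table))
    table <- table[table$label == "unlabeled", , drop = FALSE]
  if (!"group" %in% names(table)) table$group <- NA_character_
  shares <- do.call(rbind, lapply(split(
    table, interaction(table$class, table$sample, drop = TRUE)),
    function(sub) {
      tot <- sum(sub$intensity)
      if (tot == 0) {
        warning("class ", sub$class[1L], " empty in sample ",
                sub$sample[1L], "; skipped")
        return(NULL)
      }
      data.frame(class = sub$class, carbons = sub$carbons,
                 double_bonds = sub$double_bonds, sample = sub$sample,
                 group = sub$group, share = sub$intensity / tot,
                 stringsAsFactors = FALSE)
    }))
  rownames(shares) <- NULL

  tests <- NULL
  grps <- if (!is.null(compare)) compare else
    sort(unique(shares$group[!is.na(shares$group)]))
  if (length(grps) == 2L) {
    key <- interaction(shares$class, shares$carbons, shares$double_bonds,
                       drop = TRUE)
    tests <- do.call(rbind, lapply(split(shares, key), function(sub) {
      sa <- sub$share[sub$group == grps[1L]]
      sb <- sub$share[sub$group == grps[2L]]
      p <- if (length(sa) >= 2L && length(sb) >= 2L &&
               (stats::sd(sa) > 0 || stats::sd(sb) > 0))
        stats::t.test(sa, sb, var.equal = TRUE)$p.value else NA_real_
      data.frame(class = sub$class[1L], carbons = sub$carbons[1L],
                 double_bonds = sub$double_bonds[1L],
                 mean_a = mean(sa), mean_b = mean(sb), p_value = p,
                 stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  list(shares = shares, tests = tests)
}

#' Isotope-labeling flux ratios along a precursor chain
#'
#' For each class with a precursor in `precursor_map` (default the
#' CDP-DAG order PS -> PE -> PC), the labeled product intensity is
#' divided by the labeled precursor intensity at each timepoint
#' (precursor-normalized conversion readout); every class additionally
#' gets the labeled / unlabeled same-class ratio (label uptake
#' readout). Intensities are summed over species within a class at each
#' timepoint. Zero denominators give `NA` at that timepoint.
#'
#' @param table long-format lipid table with `label` ("unlabeled" /
#'   "15N") and `timepoint` columns.
#' @param precursor_map named character vector, product -> precursor.
#' @return data.frame: `class`, `timepoint`, `labeled`, `unlabeled`,
#'   `ratio_to_precursor`, `ratio_to_unlabeled`.
#' @export
flux_ratios <- function(table, precursor_map = c(PE = "PS", PC = "PE")) {
  table <- validate_lipid_table(table)
  if (!"timepoint" %in% names(table))
    stop("flux_ratios() needs a timepoint column")
  agg <- stats::aggregate(intensity ~ class + label + timepoint,
                          data = table, FUN = sum)
  classes <- unique(agg$class); tps <- sort(unique(agg$timepoint))
  get <- function(cl, lab, tp) {
    v <- agg$intensity[agg$class == cl & agg$label == lab &
                         agg$timepoint == tp]
    if (length(v)) v else 0
  }
  out <- expand.grid(class = classes, timepoint = tps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$labeled <- mapply(get, out$class, "15N", out$timepoint)
  out$unlabeled <- mapply(get, out$class, "unlabeled", out$timepoint)
  pre <- precursor_map[out$class]
  pre_lab <- ifelse(is.na(pre), NA_real_,
                    mapply(function(p, tp) if (is.na(p)) NA_real_
                           else get(p, "15N", tp), pre, out$timepoint))
  out$ratio_to_precursor <- ifelse(
    is.na(pre) | pre_lab == 0, NA_real_, out$labeled / pre_lab)
  out$ratio_to_unlabeled <- ifelse(
    out$unlabeled == 0, NA_real_, out$labeled / out$unlabeled)
  na_den <- (!is.na(pre) & pre_lab == 0) | out$unlabeled == 0
  if (any(na_den))
    message(sum(na_den), " ratio(s) undefined (zero denominator)")
  out[order(out$class, out$timepoint), , drop = FALSE]
}
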