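#' @include AllClasses.R hic-io.R utils.R
NULL

#' Enumerate cell-type combinations for the simulation design
#'
#' All subsets of at least `min_size` of `n_types` cell types, the full
#' census of mixture designs. Order is deterministic: by subset size, then
#' lexicographically.
#'
#' @param n_types Number of cell types, or a character vector of labels.
#' @param min_size Minimum subset size (default 2: true mixtures only).
#' @return List of subsets (integer indices, or labels when labels were
#'   given).
#' @examples
#' length(enumerateCombinations(4, 2))  # 11
#' @export
enumerateCombinations <- function(n_types, min_size = 2) {
  labels <- NULL
  if (is.character(n_types)) {
    labels <- n_types
    n_types <- length(labels)
  }
  if (min_size < 1 || min_size > n_types)
    stop("empty design: min_size must lie in [1, n_types]")
  out <- list()
  for (s in seq(min_size, n_types)) {
    cmb <- utils::combn(n_types, s)
    for (j in seq_len(ncol(cmb))) {
      sub <- cmb[, j]
      out[[length(out) + 1L]] <- if (is.null(labels)) sub else labels[sub]
    }
  }
  out
}

#' Draw a random mixture composition on a cell-type subset
#'
#' For each type in `subset`, draws `r_i ~ Uniform(0, 1)` i.i.d. and sets
#' `f_i = r_i / sum(r)`, rounded to three decimals; types outside the
#' subset get fraction 0.
#'
#' @param subset Character labels (or indices into `cell_types`) of the
#'   types present in the mixture.
#' @param cell_types Full ordered label set of the design.
#' @param seed Integer seed for the draw.
#' @return A [MixtureSpec-class] over the full type set.
#' @export
drawFractions <- function(subset, cell_types, seed) {
  if (is.numeric(subset)) subset <- cell_types[subset]
  if (length(subset) == 0) stop("subset must be non-empty")
  stopifnot(all(subset %in% cell_types))
  f <- .with_substream(seed, "fractions", {
    repeat {
      r <- stats::runif(length(subset))
      if (sum(r) > 0) break
    }
    # three-decimal rounding, sum-preserving: allocate 1000 thousandths by
    # largest remainder so the fractions stay on the simplex for any K
    .largest_remainder(r / sum(r), 1000L) / 1000
  })
  full <- stats::setNames(numeric(length(cell_types)), cell_types)
  full[subset] <- f
  new("MixtureSpec", cellTypes = cell_types, fractions = unname(full),
      seed = as.integer(seed))
}

#' Per-type cell and contact allocations
#'
#' `cellsPerType` converts fractions into integer cell counts
#' `N_i ~ n_sum * f_i`; `contactsPerType` does the same for contact counts
#' `M_i ~ m_sum * f_i`. Both use largest-remainder rounding so the counts
#' sum to the requested total exactly.
#'
#' @param spec A [MixtureSpec-class].
#' @param n_sum,m_sum Total number of cells / contacts in the bulk sample.
#' @return Named integer vector over the spec's cell types.
#' @export
cellsPerType <- function(spec, n_sum) {
  f <- fractions(spec)
  if (n_sum < sum(f > 0))
    warning("n_sum smaller than the number of mixed types; ",
            "some types will receive zero cells")
  stats::setNames(.largest_remainder(unname(f), n_sum), names(f))
}

#' @rdname cellsPerType
#' @export
contactsPerType <- function(spec, m_sum) {
  f <- fractions(spec)
  if (m_sum < sum(f > 0))
    warning("m_sum smaller than the number of mixed types; ",
            "some types will receive zero contacts")
  stats::setNames(.largest_remainder(unname(f), m_sum), names(f))
}

#' Draw a bulk library size
#'
#' Uniform draw of the total contact count of a simulated bulk library.
#' The default range matches deeply sequenced tissue Hi-C libraries
#' (1.48e8 to 2.35e8 contacts); pass a smaller range for desk-scale
#' simulations.
#'
#' @param seed Integer seed.
#' @param lo,hi Range bounds (inclusive).
#' @return Integer library size.
#' @export
drawLibrarySize <- function(seed, lo = 148054505, hi = 235282624) {
  .with_substream(seed, "library_size",
                  as.integer(round(stats::runif(1, lo, hi))))
}

## Template pools -------------------------------------------------------------

# Flatten a template into its contact multiset: one row per (chrom, i <= j)
# pair with an integer count.
.template_pool <- function(template) {
  recs <- lapply(names(template@matrices), function(ch) {
    v <- contactValues(template@matrices[[ch]])
    ut <- which(upper.tri(v, diag = TRUE) & v > 0, arr.ind = TRUE)
    data.frame(chrom_a = ch, bin_a = ut[, 1] - 1L, chrom_b = ch,
               bin_b = ut[, 2] - 1L, count = as.integer(round(v[ut])))
  })
  out <- do.call(rbind, recs)
  out[out$count > 0, , drop = FALSE]
}

# Draw n contacts without replacement from a pool data.frame (multiset of
# sum(count) contacts). Falls back to with-replacement (with a message)
# only when n exceeds the pool size.
.sample_pool <- function(pool, n) {
  total <- sum(pool$count)
  if (n == 0)
    return(pool[0, , drop = FALSE])
  if (n > total) {
    message("requested ", n, " contacts from a pool of ", total,
            "; sampling with replacement")
    draw <- sample.int(total, n, replace = TRUE)
  } else {
    draw <- sample.int(total, n)
  }
  cum <- cumsum(pool$count)
  idx <- findInterval(draw - 0.5, c(0, cum))
  cnt <- tabulate(idx, nbins = nrow(pool))
  out <- pool[cnt > 0, , drop = FALSE]
  out$count <- cnt[cnt > 0]
  rownames(out) <- NULL
  out
}

#' Pool single cells of one type into a template
#'
#' Aggregates per-cell contact lists of one cell type into the pooled pure
#' profile used as a sampling pool for in-silico single-cell generation.
#'
#' @param cells List of [ContactList-class], one per cell.
#' @param cell_type Label for the pooled type.
#' @param n_bins Bins per chromosome; by default the maximum bin index + 1
#'   observed across cells.
#' @return A [CellTypeTemplate-class].
#' @export
poolCellType <- function(cells, cell_type = "type", n_bins = NULL) {
  stopifnot(length(cells) > 0)
  res <- resolution(cells[[1]])
  all_rec <- do.call(rbind, lapply(cells, records))
  merged <- contactList(all_rec, res)
  chroms <- sort(unique(c(merged@records$chrom_a, merged@records$chrom_b)))
  if (is.null(n_bins))
    n_bins <- max(merged@records$bin_a, merged@records$bin_b) + 1L
  mats <- lapply(chroms, function(ch) toMatrix(merged, ch, n_bins))
  names(mats) <- chroms
  total <- sum(vapply(mats, function(m) {
    v <- contactValues(m)
    sum(v[upper.tri(v, diag = TRUE)])
  }, numeric(1)))
  new("CellTypeTemplate", cellType = cell_type, matrices = mats,
      totalContacts = total)
}

#' Synthesise a single cell by downsampling a pooled template
#'
#' Draws `n_contacts` contacts without replacement from the template's
#' pooled contact multiset, emulating the sparse contact list of one cell.
#'
#' @param template A [CellTypeTemplate-class].
#' @param n_contacts Number of contacts to draw (typically the median
#'   per-cell contact count of the type).
#' @param seed Integer seed.
#' @return A [ContactList-class].
#' @export
synthSingleCell <- function(template, n_contacts, seed = 1) {
  if (n_contacts > template@totalContacts)
    stop(sprintf("cannot draw %d contacts from a pool of %d without replacement",
                 n_contacts, as.integer(template@totalContacts)))
  res <- resolution(template@matrices[[1]])
  pool <- .template_pool(template)
  rec <- .with_substream(seed, paste0("cell_", template@cellType),
                         .sample_pool(pool, n_contacts))
  contactList(rec, res)
}

#' Simulate a bulk sample as a population of single cells
#'
#' Samples `N_i = n_sum * f_i` cells per type (largest-remainder rounded)
#' from the supplied per-type cell lists, topping up with in-silico cells
#' drawn from the pooled template when a type has fewer real cells than
#' requested, and merges all their contacts.
#'
#' @param per_type_cells Named list (by cell type) of lists of
#'   [ContactList-class] cells.
#' @param spec The ground-truth [MixtureSpec-class].
#' @param n_sum Total number of cells in the population (default 1000).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A [BulkSample-class] whose provenance records the per-type cell
#'   counts.
#' @export
synthesizeBulkFromCells <- function(per_type_cells, spec, n_sum = 1000,
                                    seed = 1, sample_id = "bulk") {
  n_i <- cellsPerType(spec, n_sum)
  res <- resolution(per_type_cells[[1]][[1]])
  picked <- list()
  for (ct in names(n_i)) {
    need <- n_i[[ct]]
    if (need == 0) next
    avail <- per_type_cells[[ct]]
    if (is.null(avail)) stop("no cells supplied for type ", ct)
    take <- .with_substream(seed, paste0("cells_", ct), {
      if (need <= length(avail)) {
        avail[sample.int(length(avail), need)]
      } else {
        template <- poolCellType(avail, ct)
        n_med <- stats::median(vapply(avail, totalContacts, numeric(1)))
        extra <- lapply(seq_len(need - length(avail)), function(j)
          synthSingleCell(template, n_med, seed = .substream_seed(
            seed, paste0("extra_", ct, "_", j))))
        c(avail, extra)
      }
    })
    picked[[ct]] <- take
  }
  all_rec <- do.call(rbind, lapply(unlist(picked, recursive = FALSE),
                                   records))
  new("BulkSample", spec = spec, contacts = contactList(all_rec, res),
      provenance = stats::setNames(as.numeric(n_i), names(n_i)),
      sampleId = sample_id)
}

#' Simulate a bulk sample by sampling contacts from pure profiles
#'
#' Draws `M_i = m_sum * f_i` contacts (largest-remainder rounded) from each
#' type's pooled contact multiset without replacement and merges them,
#' emulating a bulk library assembled from pure cell-line libraries.
#'
#' @param templates Named list (by cell type) of
#'   [CellTypeTemplate-class].
#' @param spec The ground-truth [MixtureSpec-class].
#' @param m_sum Total contact count of the simulated library.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A [BulkSample-class] whose provenance records the per-type
#'   contact counts `M_i`.
#' @export
synthesizeBulkFromPure <- function(templates, spec, m_sum, seed = 1,
                                   sample_id = "bulk") {
  m_i <- contactsPerType(spec, m_sum)
  res <- resolution(templates[[1]]@matrices[[1]])
  recs <- list()
  for (ct in names(m_i)) {
    if (m_i[[ct]] == 0) next
    tpl <- templates[[ct]]
    if (is.null(tpl)) stop("no template supplied for type ", ct)
    pool <- .template_pool(tpl)
    recs[[ct]] <- .with_substream(seed, paste0("contacts_", ct),
                                  .sample_pool(pool, m_i[[ct]]))
  }
  all_rec <- do.call(rbind, recs)
  new("BulkSample", spec = spec, contacts = contactList(all_rec, res),
      provenance = stats::setNames(as.numeric(m_i), names(m_i)),
      sampleId = sample_id)
}

#' Generate synthetic cell-type templates
#'
#' Builds `k` per-type contact-map templates that share a common
#' distance-decay backbone `P(d) ~ (1 + d)^-decay` but differ in
#' compartment-scale structure: each type carries its own block-structured
#' A/B checkerboard (strength `compartment`) and a few type-specific
#' enriched squares on the diagonal (TAD-like domains, fold-change
#' `enrichment`). Types are therefore globally similar yet separable, the
#' regime in which deconvolution is non-trivial.
#'
#' @param k Number of cell types.
#' @param n_bins Bins per chromosome.
#' @param n_chroms Number of chromosomes.
#' @param structure_seed Integer seed controlling all structure draws.
#' @param total_per_chrom Target contact sum per chromosome (upper triangle
#'   counted once).
#' @param decay Distance-decay exponent.
#' @param compartment Checkerboard modulation strength in `[0, 1)`.
#' @param block_size Bins per compartment block.
#' @param n_domains Enriched diagonal squares per chromosome and type.
#' @param domain_size Side length of an enriched square, in bins.
#' @param enrichment Multiplicative enrichment of domain squares.
#' @param resolution Base pairs per bin (metadata only).
#' @return List of `k` [CellTypeTemplate-class], named `type1..typek`.
#' @export
makeTemplates <- function(k, n_bins = 50, n_chroms = 2, structure_seed = 1,
                          total_per_chrom = 5e5, decay = 1,
                          compartment = 0.4, block_size = 5, n_domains = 3,
                          domain_size = 4, enrichment = 2.5,
                          resolution = 5e5) {
  stopifnot(k >= 1, n_bins >= 2 * domain_size, compartment >= 0,
            compartment < 1)
  chroms <- paste0("chr", seq_len(n_chroms))
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  backbone <- (1 + d)^(-decay)
  n_blocks <- ceiling(n_bins / block_size)
  .with_substream(structure_seed, "templates", {
    out <- lapply(seq_len(k), function(t) {
      mats <- lapply(chroms, function(ch) {
        signs <- sample(c(-1, 1), n_blocks, replace = TRUE)
        s <- rep(signs, each = block_size)[seq_len(n_bins)]
        m <- backbone * (1 + compartment * outer(s, s))
        for (q in seq_len(n_domains)) {
          at <- sample.int(n_bins - domain_size + 1L, 1)
          span <- at:(at + domain_size - 1L)
          m[span, span] <- m[span, span] * enrichment
        }
        ut_sum <- sum(m[upper.tri(m, diag = TRUE)])
        m <- round(m * total_per_chrom / ut_sum)
        contactMatrix(m, chrom = ch, resolution = resolution)
      })
      names(mats) <- chroms
      total <- sum(vapply(mats, function(m) {
        v <- contactValues(m)
        sum(v[upper.tri(v, diag = TRUE)])
      }, numeric(1)))
      new("CellTypeTemplate", cellType = paste0("type", t),
          matrices = mats, totalContacts = total)
    })
    names(out) <- paste0("type", seq_len(k))
    out
  })
}

#' Distance of a candidate mixture to a training design
#'
#' Minimum Euclidean distance between the candidate's fraction vector and
#' any training spec's, aligned on the union of the cell-type sets (absent
#' types count as 0).
#'
#' @param candidate A [MixtureSpec-class].
#' @param training List of [MixtureSpec-class].
#' @return Non-negative numeric.
#' @export
minDistanceToTraining <- function(candidate, training) {
  stopifnot(length(training) > 0)
  types <- unique(c(cellTypes(candidate),
                    unlist(lapply(training, cellTypes))))
  align <- function(spec) {
    v <- stats::setNames(numeric(length(types)), types)
    v[cellTypes(spec)] <- fractions(spec)
    v
  }
  cv <- align(candidate)
  min(vapply(training, function(tr) sqrt(sum((cv - align(tr))^2)),
             numeric(1)))
}

#' Select distal unseen mixtures
#'
#' Ranks candidate mixtures by their minimum distance to the training
#' design and keeps the most distal ones: either those beyond the stated
#' quantile of the candidate distance distribution (default top 10%), or --
#' in `"peaks"` mode -- those beyond the third local maximum of a kernel
#' density estimate of the distances, when at least three peaks exist.
#'
#' @param candidates List of [MixtureSpec-class].
#' @param training List of [MixtureSpec-class].
#' @param quantile Distance quantile defining "distal" (default 0.90).
#' @param mode `"quantile"` (default) or `"peaks"`.
#' @return The selected subset of `candidates`, most distal first; the
#'   distances are attached as attribute `minDistance`.
#' @export
selectDistalUnseen <- function(candidates, training, quantile = 0.90,
                               mode = c("quantile", "peaks")) {
  mode <- match.arg(mode)
  d <- vapply(candidates, minDistanceToTraining, numeric(1),
              training = training)
  n <- length(d)
  if (mode == "quantile") {
    keep_n <- n - floor(quantile * n)
    ord <- order(-d, seq_len(n))
    sel <- ord[seq_len(keep_n)]
  } else {
    dens <- stats::density(d)
    y <- dens$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(peaks) >= 3) {
      thr <- dens$x[peaks[3]]
      sel <- which(d > thr)
      sel <- sel[order(-d[sel], sel)]
    } else {
      # fewer than three density peaks: fall back to the quantile rule
      keep_n <- n - floor(quantile * n)
      ord <- order(-d, seq_len(n))
      sel <- ord[seq_len(keep_n)]
    }
  }
  out <- candidates[sel]
  attr(out, "minDistance") <- d[sel]
  out
}
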