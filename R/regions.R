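## Partition of the genome into analysis regions. LD blocks tile each
## chromosome; a gene belongs to the block containing all its model variants,
## and blocks spanned by any gene's model are merged (transitively) into one
## region. Variants are assigned by position via GenomicRanges overlap.

#' Assign variants and genes to analysis regions
#'
#' Builds the region partition: every variant falls in the LD block covering
#' its position; every gene is assigned to the block(s) containing its model
#' variants, and all blocks touched by one gene are merged into a single
#' region (transitively, so overlapping spans collapse by union-find into one
#' region).  Genes whose model variants lie on two chromosomes, or outside the
#' block tiling, are rejected.
#'
#' @param blocks data.frame of block definitions: \code{chrom}, \code{start},
#'   \code{stop} (half-open, 0-based, BED convention), \code{block_id}.
#' @param variants data.frame of harmonized variants (\code{variant_id},
#'   \code{chrom}, \code{pos}).
#' @param weight_models list of harmonized \code{\link{WeightModel}} objects.
#' @return a \code{\link{RegionIndex}}.
#' @export
assignRegions <- function(blocks, variants, weight_models = list()) {
    stopifnot(all(c("chrom", "start", "stop", "block_id") %in% colnames(blocks)),
              all(blocks$start < blocks$stop))
    bgr <- GenomicRanges::GRanges(
        seqnames = blocks$chrom,
        ranges = IRanges::IRanges(start = blocks$start + 1L, end = blocks$stop)
    )
    vgr <- GenomicRanges::GRanges(
        seqnames = variants$chrom,
        ranges = IRanges::IRanges(start = variants$pos, width = 1L)
    )
    hits <- GenomicRanges::findOverlaps(vgr, bgr, select = "first")
    if (anyNA(hits)) {
        warning(sum(is.na(hits)), " variant(s) outside the block tiling dropped")
        variants <- variants[!is.na(hits), , drop = FALSE]
        hits <- hits[!is.na(hits)]
    }
    variant_block <- blocks$block_id[hits]

    ## union-find over blocks, driven by gene model spans
    parent <- seq_len(nrow(blocks))
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    unite <- function(i, j) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
    }
    vkey <- paste(variants$chrom, variants$pos, sep = ":")
    gene_blocks <- list()
    rejected <- character()
    for (m in weight_models) {
        mk <- paste(m@variants$chrom, m@variants$pos, sep = ":")
        idx <- match(mk, vkey)
        if (anyNA(idx)) {
            rejected[m@gene_id] <- "model variant absent from the harmonized variant set"
            next
        }
        if (length(unique(m@variants$chrom)) > 1L) {
            rejected[m@gene_id] <- "model variants on two chromosomes"
            next
        }
        bids <- unique(variant_block[idx])
        gene_blocks[[m@gene_id]] <- bids
        bi <- match(bids, blocks$block_id)
        if (length(bi) > 1L) for (k in seq_along(bi)[-1L]) unite(bi[1L], bi[k])
    }
    root <- vapply(seq_len(nrow(blocks)), find, integer(1L))

    region_of_block <- character(nrow(blocks))
    regions <- list()
    for (r in unique(root)) {
        members <- which(root == r)
        rid <- paste(sort(blocks$block_id[members]), collapse = "+")
        region_of_block[members] <- rid
        regions[[rid]] <- data.frame(
            region_id = rid,
            chrom = blocks$chrom[members[1L]],
            start = min(blocks$start[members]),
            stop = max(blocks$stop[members]),
            member_blocks = paste(sort(blocks$block_id[members]), collapse = ","),
            stringsAsFactors = FALSE
        )
    }
    regions <- do.call(rbind, c(unname(regions), list(make.row.names = FALSE)))

    variant_region <- region_of_block[match(variant_block, blocks$block_id)]
    ord <- order(variants$chrom, variants$pos)
    region_variants <- split(variants$variant_id[ord], variant_region[ord])
    region_genes <- lapply(setNames(regions$region_id, regions$region_id), function(rid) character(0))
    for (g in names(gene_blocks)) {
        rid <- region_of_block[match(gene_blocks[[g]][1L], blocks$block_id)]
        region_genes[[rid]] <- c(region_genes[[rid]], g)
    }
    empty <- setdiff(regions$region_id, names(region_variants))
    region_variants[empty] <- replicate(length(empty), character(0), simplify = FALSE)

    new("RegionIndex",
        regions = regions,
        region_variants = region_variants[regions$region_id],
        region_genes = region_genes[regions$region_id],
        rejected_genes = rejected
    )
}

#' Deterministic variant thinning mask
#'
#' Keeps one variant in every \code{ceiling(1 / keep_fraction)} by position
#' order, starting at a seed-derived offset.  A deterministic stride (rather
#' than Bernoulli sampling) makes the thinned set reproducible and evenly
#' spaced; the seed only moves the stride phase.
#'
#' @param n_variants number of variants in the region (in position order).
#' @param keep_fraction fraction to keep, in (0, 1].
#' @param seed integer controlling the stride offset.
#' @return logical mask of length \code{n_variants}.
#' @export
thinVariants <- function(n_variants, keep_fraction = 0.1, seed = 0L) {
    stopifnot(keep_fraction > 0, keep_fraction <= 1)
    if (n_variants == 0L) return(logical(0L))
    stride <- ceiling(1 / keep_fraction)
    offset <- as.integer(seed %% stride)
    mask <- rep(FALSE, n_variants)
    mask[seq.int(1L + offset, n_variants, by = stride)] <- TRUE
    if (!any(mask)) mask[1L + offset %% n_variants] <- TRUE
    mask
}

#' Random variant cap mask
#'
#' Identity when the region holds at most \code{max_variants}; otherwise a
#' uniform random subset of exactly \code{max_variants}, reproducible by seed.
#'
#' @param n_variants number of variants.
#' @param max_variants cap (default 20000).
#' @param seed integer seed for the subset draw.
#' @return logical mask of length \code{n_variants}.
#' @export
capVariants <- function(n_variants, max_variants = 20000L, seed = 0L) {
    stopifnot(max_variants >= 1L)
    if (n_variants <= max_variants) return(rep(TRUE, n_variants))
    mask <- rep(FALSE, n_variants)
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
    mask[sample.int(n_variants, max_variants)] <- TRUE
    mask
}

## save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        get(".Random.seed", envir = globalenv())
    } else {
        NULL
    }
}

.Random.seed.restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
}

## stable small integer derived from a region id, used to decorrelate
## per-region seeds independently of processing order
.regionSeedOffset <- function(region_id) {
    sum(utf8ToInt(region_id) * seq_along(utf8ToInt(region_id))) %% 104729L
}
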