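## Plain-text on-disk formats. All tables are tab-delimited with a header.
## Sumstats: CHR POS A1 A2 (Z | BETA SE) N, where A1 is the effect
## (alternate) allele and A2 the other (reference) allele. Weights: GENE CHR
## POS A1 A2 WEIGHT plus a YAML manifest declaring the weight scale. LD: a
## BED-like block table, and per block a headerless numeric correlation
## matrix plus a variant sidecar table.

#' Read GWAS summary statistics
#'
#' Tab-delimited with header: \code{CHR}, \code{POS}, \code{A1} (effect /
#' alternate allele), \code{A2} (reference allele), and either \code{Z} or
#' \code{BETA} + \code{SE} (in which case \code{z = BETA / SE} is computed on
#' read), plus \code{N}.
#'
#' @param path file path.
#' @return data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{allele_ref}, \code{allele_alt}, \code{z}, \code{n}.
#' @export
readGwas <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df) <- toupper(names(df))
    need <- c("CHR", "POS", "A1", "A2", "N")
    stopifnot(all(need %in% names(df)))
    z <- if ("Z" %in% names(df)) {
        df$Z
    } else if (all(c("BETA", "SE") %in% names(df))) {
        df$BETA / df$SE
    } else {
        stop("sumstats must provide Z or BETA and SE")
    }
    bad <- !is.finite(z)
    if (any(bad)) {
        warning(sum(bad), " variant(s) with non-finite z dropped on read")
    }
    out <- data.frame(
        variant_id = paste(df$CHR, df$POS, sep = ":"),
        chrom = as.character(df$CHR), pos = as.integer(df$POS),
        allele_ref = df$A2, allele_alt = df$A1,
        z = z, n = as.integer(df$N), stringsAsFactors = FALSE
    )
    out[!bad, , drop = FALSE]
}

#' Read eQTL weight models
#'
#' Tab-delimited with header \code{GENE}, \code{CHR}, \code{POS}, \code{A1}
#' (effect allele), \code{A2}, \code{WEIGHT}.  The weight scale
#' (\code{standardized} or \code{per_allele}) comes from the YAML manifest
#' (key \code{scale}) or the \code{scale} argument.
#'
#' @param path weight table path.
#' @param manifest optional path to a YAML manifest.
#' @param scale weight scale when no manifest is given.
#' @return named list of \code{\link{WeightModel}} objects.
#' @export
readWeightModels <- function(path, manifest = NULL, scale = "standardized") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df) <- toupper(names(df))
    stopifnot(all(c("GENE", "CHR", "POS", "A1", "A2", "WEIGHT") %in% names(df)))
    if (!is.null(manifest)) {
        man <- yaml::read_yaml(manifest)
        scale <- man$scale %||% scale
    }
    out <- lapply(split(df, df$GENE), function(d) {
        d <- d[order(d$CHR, d$POS), , drop = FALSE]
        new("WeightModel",
            gene_id = d$GENE[1L],
            chrom = as.character(d$CHR[1L]),
            tss_pos = as.integer(d$POS[1L]),
            variants = data.frame(
                variant_id = paste(d$CHR, d$POS, sep = ":"),
                chrom = as.character(d$CHR), pos = as.integer(d$POS),
                allele_ref = d$A2, allele_alt = d$A1,
                stringsAsFactors = FALSE
            ),
            weights = d$WEIGHT,
            scale = scale
        )
    })
    out[order(names(out))]
}

#' Read pairwise weight-variant covariances
#'
#' Tab-delimited with header \code{GENE}, \code{VAR1}, \code{VAR2},
#' \code{COV} (the training-panel covariances shipped with per-allele weight
#' databases; used to resolve strand-ambiguous weights).
#'
#' @param path file path.
#' @return data.frame with columns \code{gene}, \code{var1}, \code{var2},
#'   \code{cov}.
#' @export
readWeightCovariances <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df) <- toupper(names(df))
    stopifnot(all(c("GENE", "VAR1", "VAR2", "COV") %in% names(df)))
    data.frame(
        gene = df$GENE, var1 = df$VAR1, var2 = df$VAR2, cov = df$COV,
        stringsAsFactors = FALSE
    )
}

#' Read block definitions
#'
#' BED-like tab-delimited table with header \code{chrom}, \code{start},
#' \code{stop}, \code{block_id}; half-open, 0-based.
#'
#' @param path file path.
#' @return the block data.frame.
#' @export
readBlockDefinitions <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "stop", "block_id") %in% names(df)))
    df$start <- as.integer(df$start)
    df$stop <- as.integer(df$stop)
    df$block_id <- as.character(df$block_id)
    df
}

#' Read per-block LD matrices
#'
#' Expects, under \code{dir}, a \code{blocks.tsv} block table plus, per
#' block, \code{<block_id>.vars.tsv} (variant sidecar: \code{block_id},
#' \code{CHR}, \code{POS}, \code{A1}, \code{A2}, \code{MAF}) and
#' \code{<block_id>.ld.tsv} (headerless numeric correlation matrix).
#'
#' @param dir directory path.
#' @return list with \code{blocks} (data.frame) and \code{ld} (named list of
#'   \code{\link{LDBlock}}).
#' @export
readLdBlocks <- function(dir) {
    blocks <- readBlockDefinitions(file.path(dir, "blocks.tsv"))
    ld <- lapply(blocks$block_id, function(bid) {
        vt <- read.delim(file.path(dir, paste0(bid, ".vars.tsv")),
                         stringsAsFactors = FALSE)
        names(vt) <- toupper(names(vt))
        R <- as.matrix(read.delim(file.path(dir, paste0(bid, ".ld.tsv")),
                                  header = FALSE))
        dimnames(R) <- NULL
        new("LDBlock",
            block_id = bid,
            variants = data.frame(
                variant_id = paste(vt$CHR, vt$POS, sep = ":"),
                chrom = as.character(vt$CHR), pos = as.integer(vt$POS),
                allele_ref = vt$A2, allele_alt = vt$A1, maf = vt$MAF,
                stringsAsFactors = FALSE
            ),
            corr = R
        )
    })
    names(ld) <- blocks$block_id
    list(blocks = blocks, ld = ld)
}

#' Write a simulated bundle in the on-disk input formats
#'
#' Emits exactly what the readers consume: \code{sumstats.tsv},
#' \code{weights.tsv} + \code{weights_manifest.yaml}, \code{blocks.tsv}, and
#' per-block \code{*.vars.tsv} / \code{*.ld.tsv}, so a full run is possible
#' with zero downloads.
#'
#' @param bundle a \code{\link{SimBundle}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCtwasInputs <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    g <- bundle@gwas
    write.table(
        data.frame(CHR = g$chrom, POS = g$pos, A1 = g$allele_alt,
                   A2 = g$allele_ref, Z = g$z, N = g$n),
        file.path(dir, "sumstats.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
    )
    wt <- do.call(rbind, c(lapply(bundle@weights, function(m) {
        data.frame(GENE = m@gene_id, CHR = m@variants$chrom,
                   POS = m@variants$pos, A1 = m@variants$allele_alt,
                   A2 = m@variants$allele_ref, WEIGHT = m@weights,
                   stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
    write.table(wt, file.path(dir, "weights.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(list(scale = "standardized"),
                     file.path(dir, "weights_manifest.yaml"))
    write.table(bundle@blocks, file.path(dir, "blocks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (b in bundle@ld) {
        vt <- b@variants
        write.table(
            data.frame(block_id = b@block_id, CHR = vt$chrom, POS = vt$pos,
                       A1 = vt$allele_alt, A2 = vt$allele_ref, MAF = vt$maf),
            file.path(dir, paste0(b@block_id, ".vars.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE
        )
        write.table(b@corr, file.path(dir, paste0(b@block_id, ".ld.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    invisible(dir)
}

#' Write a results table
#'
#' @param fit a \code{\link{CtwasFit}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(fit, path) {
    write.table(fit@results, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
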