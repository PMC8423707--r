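## Linking splicing events to an externally computed differential-expression
## table (gene, log2 fold change, base mean, adjusted p) and testing whether
## cryptic-exon genes are biased towards downregulation relative to an
## expression-matched null gene set.

#' Read a differential-expression results table
#'
#' The table is consumed as input (e.g. a DESeq2 results export), never
#' computed here. Required columns: `gene`, `log2fc`, `base_mean`, `adj_p`
#' (common aliases `log2FoldChange`, `baseMean`, `padj` are accepted).
#'
#' @param path TSV path.
#' @return a `data.frame` with the four canonical columns.
#' @export
readExpressionTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    alias <- c(log2FoldChange = "log2fc", baseMean = "base_mean",
               padj = "adj_p")
    for (nm in names(alias))
        if (nm %in% colnames(d) && !alias[[nm]] %in% colnames(d))
            colnames(d)[colnames(d) == nm] <- alias[[nm]]
    need <- c("gene", "log2fc", "base_mean", "adj_p")
    if (!all(need %in% colnames(d)))
        stop("expression table needs columns ", paste(need, collapse = ", "))
    d[need]
}

#' Expression-matched null gene set
#'
#' Selects genes whose `log10(base_mean)` lies within the mean plus or minus
#' one standard deviation of the target genes' `log10(base_mean)`, excluding
#' the targets themselves and any further `excluded_genes` (typically all
#' differentially spliced genes).
#'
#' @param de_table a `data.frame` as from [readExpressionTable()].
#' @param target_genes genes whose expression distribution defines the
#'   window; must appear in `de_table` and number at least 2.
#' @param excluded_genes additional genes barred from the null set.
#' @return character vector of null-set gene identifiers.
#' @export
matchExpressionNull <- function(de_table, target_genes,
                                excluded_genes = character()) {
    target_genes <- unique(target_genes)
    if (!all(target_genes %in% de_table$gene))
        stop("target genes absent from the expression table: ",
             paste(head(setdiff(target_genes, de_table$gene), 5),
                   collapse = ", "))
    if (length(target_genes) < 2)
        stop("at least 2 target genes are required (SD undefined)")
    eligible <- de_table[de_table$base_mean > 0, ]
    lt <- log10(eligible$base_mean[eligible$gene %in% target_genes])
    lo <- mean(lt) - stats::sd(lt)
    hi <- mean(lt) + stats::sd(lt)
    l <- log10(eligible$base_mean)
    keep <- l >= lo & l <= hi &
        !eligible$gene %in% c(target_genes, excluded_genes)
    unique(eligible$gene[keep])
}

#' Downregulation bias of a gene set against a matched null
#'
#' Among the genes of each set that are differentially expressed
#' (`adj_p < fdr`), computes the proportion with `log2fc < 0` and contrasts
#' the two proportions with a chi-squared test of equal proportions (no
#' continuity correction). Proportions are over FDR-passing genes only,
#' never the full sets.
#'
#' @param de_table a `data.frame` as from [readExpressionTable()].
#' @param target_genes,null_genes disjoint gene sets.
#' @param fdr adjusted-p threshold defining "differentially expressed".
#' @return a list: `prop_target`, `prop_null`, `n_target_de`, `n_null_de`,
#'   `n_target_down`, `n_null_down`, `chi2_stat`, `p_value` (`NA` with a
#'   message when a set has no differentially expressed gene).
#' @export
downregulationBias <- function(de_table, target_genes, null_genes,
                               fdr = 0.05) {
    if (length(intersect(target_genes, null_genes)))
        stop("target and null gene sets must be disjoint")
    de_sub <- function(genes) {
        d <- de_table[de_table$gene %in% genes & !is.na(de_table$adj_p) &
                          de_table$adj_p < fdr, ]
        c(down = sum(d$log2fc < 0), n = nrow(d))
    }
    t <- de_sub(target_genes)
    n <- de_sub(null_genes)
    if (t[["n"]] == 0 || n[["n"]] == 0) {
        message("a gene set has no differentially expressed members; ",
                "bias test undefined")
        return(list(prop_target = NA_real_, prop_null = NA_real_,
                    n_target_de = t[["n"]], n_null_de = n[["n"]],
                    n_target_down = t[["down"]], n_null_down = n[["down"]],
                    chi2_stat = NA_real_, p_value = NA_real_))
    }
    test <- chisq_equal_prop(t[["down"]], t[["n"]], n[["down"]], n[["n"]])
    list(prop_target = t[["down"]] / t[["n"]],
         prop_null = n[["down"]] / n[["n"]],
         n_target_de = t[["n"]], n_null_de = n[["n"]],
         n_target_down = t[["down"]], n_null_down = n[["down"]],
         chi2_stat = test$stat, p_value = test$p)
}
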