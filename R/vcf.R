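# Benchmark VCF output with symbolic CNV alleles, and the matching reader.
# Records carry the 0-based half-open benchmark interval as 1-based POS
# (first base of the event) and END in INFO, per VCF convention.

type_to_alt <- c(GAIN = "<DUP>", LOSS = "<DEL>", LOH = "<LOH>")
alt_to_type <- stats::setNames(names(type_to_alt), type_to_alt)

#' Write a benchmark set as VCF
#'
#' One record per benchmark interval, with the CNV type encoded as a
#' symbolic allele (`<DUP>`, `<DEL>`, `<LOH>`), `END`, confidence level,
#' median copy number, and supporting technologies in INFO. Intervals are
#' sorted on write. The file round-trips losslessly through
#' [read_benchmark_vcf()].
#'
#' @param benchmark A `cnv_benchmark` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_vcf <- function(benchmark, path) {
  b <- benchmark[order(benchmark$chrom, benchmark$start, benchmark$cnv_type), ,
                 drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cnvconsensus",
    "##ALT=<ID=DUP,Description=\"Copy number gain\">",
    "##ALT=<ID=DEL,Description=\"Copy number loss\">",
    "##ALT=<ID=LOH,Description=\"Copy-neutral loss of heterozygosity\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based, inclusive)\">",
    "##INFO=<ID=CONF,Number=1,Type=String,Description=\"Consensus confidence level\">",
    "##INFO=<ID=MEDCN,Number=1,Type=Float,Description=\"Median total copy number across supporting callers\">",
    "##INFO=<ID=TECHS,Number=.,Type=String,Description=\"Supporting orthogonal technologies\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- vapply(seq_len(nrow(b)), function(i) {
    info <- sprintf("END=%d;CONF=%s;MEDCN=%s;TECHS=%s",
                    as.integer(b$end[i]), b$confidence[i],
                    ifelse(is.na(b$median_cn[i]), ".",
                           format(b$median_cn[i], digits = 10)),
                    ifelse(is.na(b$tech_support[i]) | b$tech_support[i] == "",
                           ".", b$tech_support[i]))
    sprintf("%s\t%d\tcnv_%d\tN\t%s\t.\tPASS\t%s",
            b$chrom[i], as.integer(b$start[i]) + 1L, i,
            type_to_alt[[b$cnv_type[i]]], info)
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a benchmark VCF written by [write_benchmark_vcf()]
#'
#' @param path Path to the VCF.
#' @return A `cnv_benchmark` data.frame (0-based half-open coordinates).
#' @export
read_benchmark_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  parse_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]*"), info))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, "="), "", m)
  }
  if (!length(body)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cnv_type = character(0),
                      confidence = character(0), median_cn = numeric(0),
                      tech_support = character(0))
    class(out) <- c("cnv_benchmark", class(out))
    return(out)
  }
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- fields[, 8]
  medcn <- vapply(info, parse_info, character(1), key = "MEDCN")
  techs <- vapply(info, parse_info, character(1), key = "TECHS")
  out <- data.frame(
    chrom = fields[, 1],
    start = as.numeric(fields[, 2]) - 1,
    end = as.numeric(vapply(info, parse_info, character(1), key = "END")),
    cnv_type = unname(alt_to_type[fields[, 5]]),
    confidence = vapply(info, parse_info, character(1), key = "CONF"),
    median_cn = suppressWarnings(as.numeric(ifelse(medcn == ".", NA, medcn))),
    tech_support = ifelse(techs == ".", "", techs),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("cnv_benchmark", class(out))
  out
}
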