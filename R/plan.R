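#' Sequencing run planning helpers
#'
#' Small arithmetic helpers used when sizing a UMI-linked consensus
#' sequencing run: how many raw reads a target oversampling needs, the data
#' volume they occupy, how many consensus sequences a flow cell can yield at
#' a given coverage, and how many occupied droplets a screen interrogates.
#'
#' @param n_fragments Number of distinct UMI-tagged fragments to cover.
#' @param coverage Reads per fragment (oversampling).
#' @return `plan_reads_required()`: total raw reads needed.
#' @export
#' @examples
#' plan_reads_required(9000, 100)                  # raw reads for 100x
#' plan_data_volume_gb(900000, 1250)               # gigabases they occupy
#' plan_consensus_yield(10, 2000, 50)              # consensus seqs per cell
#' plan_occupied_droplets(1e6, 0.25)               # cells screened
plan_reads_required <- function(n_fragments, coverage) {
  n_fragments * coverage
}

#' @rdname plan_reads_required
#' @param n_reads Raw read count.
#' @param read_length Read (fragment) length in bases.
#' @return `plan_data_volume_gb()`: data volume in Gb (1e9 bases).
#' @export
plan_data_volume_gb <- function(n_reads, read_length) {
  n_reads * read_length / 1e9
}

#' @rdname plan_reads_required
#' @param flowcell_gb Flow-cell capacity in Gb.
#' @param gene_length Amplicon length in bases.
#' @return `plan_consensus_yield()`: number of consensus sequences.
#' @export
plan_consensus_yield <- function(flowcell_gb, gene_length, coverage) {
  flowcell_gb * 1e9 / (gene_length * coverage)
}

#' @rdname plan_reads_required
#' @param n_droplets Total droplets generated.
#' @param occupancy Fraction of droplets containing a cell.
#' @return `plan_occupied_droplets()`: number of occupied droplets.
#' @export
plan_occupied_droplets <- function(n_droplets, occupancy) {
  n_droplets * occupancy
}
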