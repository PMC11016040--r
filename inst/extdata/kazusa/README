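Synthetic codon usage tables in Codon Usage Database (Kazusa) text format.

These are NOT the real usage tables of the named organisms. They are
stand-ins generated from the package's own synthetic-CDS generator (see
scripts/make_model_tables.R for the exact parameters and seeds), shipped so
the Kazusa parser and the host-vs-model ratio-band comparison can run
deterministically without network access. Band counts computed from them
are illustrative of the method, not reproductions of published
host/model comparisons. To analyse real organisms, download the genuine
tables from https://www.kazusa.or.jp/codon/ and pass their paths to
parse_kazusa_table().
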