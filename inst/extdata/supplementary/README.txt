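Supplementary-table inputs (user-supplied; not shipped)
=======================================================

Two acceptance checks reproduce counts from the study's published
supplementary tables. Those tables are distributed with the article
(XLSX) and are not bundled here; export them as tab-separated files with
a '#'-prefixed header into this directory:

table_s2.tsv   #library_id  filtered_reads
               one row per library, library_id in {treatment, control}:
               the usable (post-filter) read totals.

table_s3.tsv   #mirna_id  rpm_control  rpm_treatment
               one row per known mature miRNA signature.

table_s12.tsv  #mirna_id  tf_name  tf_family
               one row per predicted TF binding site in a miRNA promoter
               (upstream TF -> miRNA interactions).

table_s13.tsv  #mirna_id  tf_family
               one row per negatively correlated miRNA target family
               (downstream miRNA -> target interactions).

With these files in place, tests/testthat/test-acceptance.R recomputes
the differential-expression filter (expected: 22 passing signatures) and
the regulatory-network summary (expected: 133 edges, 16 TF families, 30
miRNA nodes in 13 families).
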