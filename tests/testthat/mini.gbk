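LOCUS       MINI01           5000 bp    DNA     linear   BCT 01-JAN-2000
DEFINITION  hand-written parser fixture.
ACCESSION   MINI01
SOURCE      .
  ORGANISM  Bacillus testis
FEATURES             Location/Qualifiers
     source          1..5000
     CDS             complement(101..220)
                     /locus_tag="MINI_0001"
                     /gene="pksS"
                     /product="Cytochrome P450"
                     /EC_number="1.14.14.-"
                     /protein_id="TP_000001.1"
                     /translation="MKVLIVGAGPAGYSAAFRCADLGLETVIVERYNTLGGVCLNVGC
                     IPSKALLHVAKVIEEAKALAEHGIVFG"
     gene            300..400
                     /locus_tag="MINI_0002"
     CDS             join(1000..1200,1300..2000)
                     /locus_tag="MINI_0003"
                     /product="Non ribosomal peptide synthetase"
     CDS             2500..2600
                     /locus_tag="MINI_0004"
                     /product="Acyl carrier protein"
                     /EC_number="2.3.3.10"
ORIGIN
//
LOCUS       MINI02           3000 bp    DNA     circular BCT 01-JAN-2000
DEFINITION  second record, zero CDS features.
ACCESSION   MINI02
SOURCE      .
  ORGANISM  Bacillus testis
FEATURES             Location/Qualifiers
     source          1..3000
ORIGIN
//
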