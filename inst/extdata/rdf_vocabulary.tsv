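term	iri
base_entry	https://glycomb.glycosmos.org/entry/
class_glycopeptide	http://purl.jp/bio/12/glyco/conjugate#Glycopeptide
class_glycoprotein	http://purl.jp/bio/12/glyco/conjugate#Glycoprotein
class_site	http://purl.jp/bio/12/glyco/conjugate#GlycosylationSite
class_saccharide	http://purl.jp/bio/12/glyco/glycan#Saccharide
rdf_type	http://www.w3.org/1999/02/22-rdf-syntax-ns#type
identifier	http://purl.org/dc/terms/identifier
peptide_sequence	http://purl.jp/bio/12/glyco/conjugate#has_peptide_sequence
protein_accession	http://purl.jp/bio/12/glyco/conjugate#has_uniprot_id
has_site	http://purl.jp/bio/12/glyco/conjugate#glycosylated_at
site_position	http://purl.jp/bio/12/glyco/conjugate#residue_number
site_residue	http://purl.jp/bio/12/glyco/conjugate#residue_name
has_glycan	http://purl.jp/bio/12/glyco/conjugate#has_saccharide
glytoucan_id	http://purl.jp/bio/12/glyco/glycan#has_glytoucan_id
composition_literal	http://purl.jp/bio/12/glyco/glycan#has_composition_notation
unmapped_flag	http://purl.jp/bio/12/glyco/glycan#composition_unverified
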