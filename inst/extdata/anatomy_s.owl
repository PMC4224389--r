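<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#"
         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">
  <owl:Ontology rdf:about="http://example.org/anatomy_s"/>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/SA_0000001">
    <rdfs:label>heart</rdfs:label>
    <oboInOwl:hasExactSynonym>cardiac organ</oboInOwl:hasExactSynonym>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/SA_0000002">
    <rdfs:label>cardiac muscle</rdfs:label>
    <oboInOwl:hasRelatedSynonym>musculus cordis</oboInOwl:hasRelatedSynonym>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/SA_0000003">
    <rdfs:label>NK-cell,  activated</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/SA_0000004">
    <rdfs:label>aorta wall</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/SA_0000005">
    <rdfs:label>embryonic heart</rdfs:label>
    <owl:deprecated rdf:datatype="http://www.w3.org/2001/XMLSchema#boolean">true</owl:deprecated>
  </owl:Class>
</rdf:RDF>
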