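<?xml version="1.0" encoding="utf-8"?>
<rdf:RDF xmlns="http://knowledgeweb.semanticweb.org/heterogeneity/alignment"
         xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:xsd="http://www.w3.org/2001/XMLSchema#">
<Alignment>
  <xml>yes</xml>
  <level>0</level>
  <type>11</type>
  <onto1>anatomy_s</onto1>
  <onto2>anatomy_t</onto2>
  <map>
    <Cell>
      <entity1 rdf:resource="http://purl.obolibrary.org/obo/SA_0000001"/>
      <entity2 rdf:resource="http://purl.obolibrary.org/obo/TA_0000001"/>
      <measure rdf:datatype="http://www.w3.org/2001/XMLSchema#float">1.0</measure>
      <relation>=</relation>
    </Cell>
  </map>
  <map>
    <Cell>
      <entity1 rdf:resource="http://purl.obolibrary.org/obo/SA_0000002"/>
      <entity2 rdf:resource="http://purl.obolibrary.org/obo/TA_0000002"/>
      <measure rdf:datatype="http://www.w3.org/2001/XMLSchema#float">1.0</measure>
      <relation>=</relation>
    </Cell>
  </map>
  <map>
    <Cell>
      <entity1 rdf:resource="http://purl.obolibrary.org/obo/SA_0000003"/>
      <entity2 rdf:resource="http://purl.obolibrary.org/obo/TA_0000003"/>
      <measure rdf:datatype="http://www.w3.org/2001/XMLSchema#float">1.0</measure>
      <relation>=</relation>
    </Cell>
  </map>
  <map>
    <Cell>
      <entity1 rdf:resource="http://purl.obolibrary.org/obo/SA_0000004"/>
      <entity2 rdf:resource="http://purl.obolibrary.org/obo/TA_0000004"/>
      <measure rdf:datatype="http://www.w3.org/2001/XMLSchema#float">1.0</measure>
      <relation>=</relation>
    </Cell>
  </map>
  <map>
    <Cell>
      <entity1 rdf:resource="http://purl.obolibrary.org/obo/SA_0000004"/>
      <entity2 rdf:resource="http://purl.obolibrary.org/obo/TA_0000002"/>
      <relation>?</relation>
    </Cell>
  </map>
</Alignment>
</rdf:RDF>
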