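<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000001</PMID>
      <Article>
        <ArticleTitle>Magnetic resonance spectroscopy in knee injury.</ArticleTitle>
        <Abstract>
          <AbstractText>Magnetic resonance spectroscopy (MRS) was performed on all patients.</AbstractText>
          <AbstractText>Magnetic resonance spectroscopy showed metabolic changes near the anterior cruciate ligament (ACL).</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000002</PMID>
      <Article>
        <ArticleTitle>A citation without an abstract.</ArticleTitle>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>1000003</PMID>
      <Article>
        <ArticleTitle>Type 2 diabetes management.</ArticleTitle>
        <Abstract>
          <AbstractText>Patients with diabetes mellitus type 2 (DM2) were enrolled. DM2 control improved under therapy.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
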